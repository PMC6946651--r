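#' Population map
#'
#' A population map assigns every sample to a population and every population
#' to a species-level group (e.g. dromedary / wild Bactrian / domestic
#' Bactrian). All statistic configurations (Fst pairs, ABBA-BABA quartets,
#' F3/F4 triples) are expressed against these labels.
#'
#' @param sample character vector of unique sample identifiers.
#' @param population character vector, same length, population label per
#'   sample.
#' @param group optional character vector of species-level group labels; if
#'   omitted the population label is reused.
#' @return A `data.frame` of class `population_map` with columns
#'   `sample`, `population`, `group`.
#' @export
population_map <- function(sample, population, group = population) {
  stopifnot(length(sample) == length(population),
            length(group) == length(population))
  if (anyDuplicated(sample)) {
    stop("duplicate sample ids in population map: ",
         paste(unique(sample[duplicated(sample)]), collapse = ", "))
  }
  out <- data.frame(sample = as.character(sample),
                    population = as.character(population),
                    group = as.character(group),
                    stringsAsFactors = FALSE)
  class(out) <- c("population_map", "data.frame")
  out
}

#' Read / write a population map TSV
#'
#' The on-disk format is a three-column tab-separated file with header
#' `sample_id`, `population`, `group`.
#'
#' @param path file path.
#' @return `read_popmap` returns a [population_map()]; `write_popmap` returns
#'   `path` invisibly.
#' @export
read_popmap <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("sample_id", "population", "group")
  if (!all(need %in% names(df))) {
    stop("population map ", path, " must have columns: ",
         paste(need, collapse = ", "))
  }
  population_map(df$sample_id, df$population, df$group)
}

#' @rdname read_popmap
#' @param popmap a [population_map()].
#' @export
write_popmap <- function(popmap, path) {
  df <- data.frame(sample_id = popmap$sample,
                   population = popmap$population,
                   group = popmap$group)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Resolve a label set (populations and/or group names) to sample ids.
# Labels may name populations or groups; unknown labels are an error.
samples_for <- function(popmap, labels) {
  hit <- popmap$population %in% labels | popmap$group %in% labels
  known <- labels %in% popmap$population | labels %in% popmap$group
  if (!all(known)) {
    stop("unknown population/group label(s): ",
         paste(labels[!known], collapse = ", "))
  }
  popmap$sample[hit]
}
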