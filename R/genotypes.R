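#' Genotype matrix container
#'
#' Sites-by-samples diploid genotype codes with per-site metadata. Codes are
#' alternate-allele dosages 0/1/2; missing genotypes (including half-calls)
#' are `NA`. Site metadata carries the fields the variant filters act on:
#' variant quality (QUAL), depth summed over samples (DP) and root-mean-square
#' mapping quality (MQ).
#'
#' @param sites data.frame with columns `chrom`, `pos` (1-based), `ref`,
#'   `alt` (comma-separated if multiallelic), `qual`, `dp`, `mq`.
#' @param geno integer matrix, `nrow(sites)` x `length(samples)`, values in
#'   `{0, 1, 2, NA}`.
#' @param samples character vector of sample ids (column order of `geno`).
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(sites, geno, samples) {
  geno <- as.matrix(geno)
  stopifnot(nrow(sites) == nrow(geno), length(samples) == ncol(geno))
  need <- c("chrom", "pos", "ref", "alt", "qual", "dp", "mq")
  miss <- setdiff(need, names(sites))
  if (length(miss)) stop("site metadata missing field(s): ",
                         paste(miss, collapse = ", "))
  bad <- !(geno %in% c(0L, 1L, 2L) | is.na(geno))
  if (any(bad)) stop("genotype codes must be 0, 1, 2 or NA")
  for (ch in unique(sites$chrom)) {
    p <- sites$pos[sites$chrom == ch]
    if (is.unsorted(p, strictly = TRUE)) {
      stop("positions not strictly increasing on chromosome ", ch)
    }
  }
  storage.mode(geno) <- "integer"
  dimnames(geno) <- list(NULL, samples)
  rownames(sites) <- NULL
  structure(list(sites = sites, geno = geno, samples = samples),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", nrow(x$geno), "sites x", ncol(x$geno), "samples;",
      length(unique(x$sites$chrom)), "chromosome(s);",
      sprintf("%.2f%%", 100 * mean(is.na(x$geno))), "missing\n")
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$geno)

# Subset sites of a genotype matrix by logical/integer index.
subset_sites <- function(gm, idx) {
  genotype_matrix(gm$sites[idx, , drop = FALSE],
                  gm$geno[idx, , drop = FALSE], gm$samples)
}

#' Genomic windows
#'
#' Tile chromosomes with non-overlapping windows (0-based, half-open). A
#' partial tail window is kept when it spans at least half of `size`,
#' otherwise it is merged arithmetic-free into nothing (dropped).
#'
#' @param chrom_lengths named numeric vector of chromosome lengths in bp.
#' @param size window size in bp.
#' @param min_tail_frac minimum fraction of `size` a tail window must span to
#'   be kept (default 0.5).
#' @return data.frame with columns `chrom`, `start`, `end`.
#' @export
make_windows <- function(chrom_lengths, size, min_tail_frac = 0.5) {
  stopifnot(size > 0, length(chrom_lengths) > 0, !is.null(names(chrom_lengths)))
  out <- lapply(names(chrom_lengths), function(ch) {
    len <- chrom_lengths[[ch]]
    starts <- seq(0, len - 1, by = size)
    ends <- pmin(starts + size, len)
    keep <- (ends - starts) >= min_tail_frac * size
    data.frame(chrom = ch, start = starts[keep], end = ends[keep])
  })
  do.call(rbind, out)
}

# Infer chromosome lengths from site positions (max position, rounded up to
# `round_to`). Used when a scan is run without explicit lengths.
infer_chrom_lengths <- function(sites, round_to = 1) {
  v <- tapply(sites$pos, sites$chrom, max)
  lens <- ceiling(v / round_to) * round_to
  stats::setNames(as.numeric(lens), names(v))
}

# Map each site to a window row index (NA when outside every window).
# Windows are assumed non-overlapping and sorted within chromosome.
assign_windows <- function(sites, windows) {
  idx <- rep(NA_integer_, nrow(sites))
  for (ch in unique(sites$chrom)) {
    w <- which(windows$chrom == ch)
    if (!length(w)) next
    w <- w[order(windows$start[w])]
    s <- which(sites$chrom == ch)
    pos0 <- sites$pos[s] - 1  # 0-based
    j <- findInterval(pos0, windows$start[w])
    ok <- j >= 1 & pos0 < windows$end[w][pmax(j, 1)]
    idx[s[ok]] <- w[j[ok]]
  }
  idx
}
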