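#' Scenario configuration for the synthetic-population generator
#'
#' The generator models allele-frequency evolution on a rooted population
#' tree under Balding-Nichols drift: along a branch with drift coefficient
#' `F`, the child frequency is Beta-distributed with mean equal to the parent
#' frequency `p` and variance `F * p * (1 - p)`. After all drift, each
#' admixture pulse mixes the donor's frequency into the recipient at
#' proportion `f`, at sites inside the pulse's window set only. Genotypes are
#' then binomial draws from the population frequencies.
#'
#' @param population_tree data.frame with columns `child`, `parent`, `F`
#'   (drift coefficient in `[0, 1)`). Leaves (children that are never
#'   parents) are the populations; exactly one node (the root) appears only
#'   as a parent.
#' @param admixture_pulses list of pulses, each a list with elements `donor`,
#'   `recipient` (population names), `f` (proportion in `[0, 1]`) and
#'   `windows` (data.frame `chrom`,`start`,`end`, 0-based half-open).
#' @param n_sites number of variant sites to simulate.
#' @param site_spacing distance in bp between consecutive sites.
#' @param chromosome_lengths named numeric vector of chromosome lengths (bp).
#' @param ancestral_freq_range length-2 numeric in (0, 1): ancestral
#'   frequencies are drawn uniformly on this interval.
#' @param target_ts_tv expected transition:transversion ratio of the drawn
#'   ref/alt allele pairs.
#' @param missing_rate per-genotype missingness probability in `[0, 1]`.
#' @param depth_model list: `mean_per_sample` (per-sample expected depth; the
#'   site DP is Poisson with mean `mean_per_sample * n_samples`).
#' @param quality_model list: `qual_mean`, `qual_sd`, `mq_mean`, `mq_sd`
#'   (normal draws, floored at 1).
#' @param samples_per_population named integer vector (or single integer
#'   recycled to all populations) of diploid sample counts.
#' @param seed integer seed; all randomness flows from it.
#' @return A validated list of class `scenario_config`.
#' @export
scenario_config <- function(population_tree,
                            admixture_pulses = list(),
                            n_sites = 10000,
                            site_spacing = 100,
                            chromosome_lengths = c(chr1 = 1e6),
                            ancestral_freq_range = c(0.05, 0.95),
                            target_ts_tv = 2.44,
                            missing_rate = 0.02,
                            depth_model = list(mean_per_sample = 10),
                            quality_model = list(qual_mean = 60, qual_sd = 15,
                                                 mq_mean = 45, mq_sd = 5),
                            samples_per_population = 10,
                            seed = 1) {
  tr <- as.data.frame(population_tree)
  if (!nrow(tr)) stop("population_tree is empty")
  stopifnot(all(c("child", "parent", "F") %in% names(tr)))
  if (any(tr$F < 0 | tr$F >= 1)) stop("drift coefficients F must be in [0, 1)")
  if (anyDuplicated(tr$child)) stop("population names/nodes must be unique")
  roots <- setdiff(tr$parent, tr$child)
  if (length(roots) != 1) stop("population_tree must have exactly one root")
  leaves <- setdiff(tr$child, tr$parent)
  if (!length(leaves)) stop("population_tree has no leaf populations")
  for (pl in admixture_pulses) {
    stopifnot(all(c("donor", "recipient", "f", "windows") %in% names(pl)))
    if (pl$f < 0 || pl$f > 1) stop("pulse proportion f must be in [0, 1]")
    if (!all(c(pl$donor, pl$recipient) %in% leaves)) {
      stop("pulse donor/recipient must be leaf populations")
    }
    w <- pl$windows
    if (nrow(w)) {
      if (!all(w$chrom %in% names(chromosome_lengths)) ||
          any(w$start < 0) ||
          any(w$end > chromosome_lengths[w$chrom])) {
        stop("pulse windows reference coordinates outside the chromosomes")
      }
    }
  }
  if (missing_rate < 0 || missing_rate > 1) stop("missing_rate must be in [0, 1]")
  stopifnot(length(ancestral_freq_range) == 2,
            ancestral_freq_range[1] > 0, ancestral_freq_range[2] < 1,
            ancestral_freq_range[1] <= ancestral_freq_range[2])
  if (length(samples_per_population) == 1 &&
      is.null(names(samples_per_population))) {
    samples_per_population <- stats::setNames(
      rep(as.integer(samples_per_population), length(leaves)), leaves)
  }
  if (!all(leaves %in% names(samples_per_population))) {
    stop("samples_per_population must cover every leaf population")
  }
  cap <- sum(floor(chromosome_lengths / site_spacing))
  if (n_sites > cap) {
    stop("n_sites exceeds chromosome capacity at the given spacing (max ",
         cap, ")")
  }
  structure(list(population_tree = tr,
                 admixture_pulses = admixture_pulses,
                 n_sites = as.integer(n_sites),
                 site_spacing = site_spacing,
                 chromosome_lengths = chromosome_lengths,
                 ancestral_freq_range = ancestral_freq_range,
                 target_ts_tv = target_ts_tv,
                 missing_rate = missing_rate,
                 depth_model = depth_model,
                 quality_model = quality_model,
                 samples_per_population = samples_per_population[leaves],
                 leaves = leaves,
                 root = roots,
                 seed = as.integer(seed)),
            class = "scenario_config")
}

# Evenly spaced site coordinates: chromosomes are filled in order, sites at
# spacing, 2*spacing, ... (1-based). Deterministic window occupancy.
site_coordinates <- function(config) {
  left <- config$n_sites
  out <- list()
  for (ch in names(config$chromosome_lengths)) {
    if (left <= 0) break
    k <- min(left, floor(config$chromosome_lengths[[ch]] / config$site_spacing))
    if (k <= 0) next
    out[[ch]] <- data.frame(chrom = ch,
                            pos = config$site_spacing * seq_len(k))
    left <- left - k
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

# One Balding-Nichols drift step: child ~ Beta with mean p, var F*p*(1-p).
# F = 0 copies the parent; boundary frequencies (0/1) are absorbing.
bn_drift <- function(p, F) {
  if (F == 0) return(p)
  out <- p
  inner <- p > 0 & p < 1
  if (any(inner)) {
    lam <- (1 - F) / F
    out[inner] <- stats::rbeta(sum(inner), lam * p[inner],
                               lam * (1 - p[inner]))
  }
  out
}

#' Simulate per-population allele frequencies with known truth
#'
#' Draws ancestral frequencies, applies Balding-Nichols drift down the
#' population tree in a fixed topological order, then applies each admixture
#' pulse (`q' = (1 - f) q + f p_donor`) at sites inside its window set.
#' Deterministic given the config seed: the draw order is (1) ancestral
#' frequencies, (2) one Beta draw block per branch in tree-row order.
#'
#' @param config a [scenario_config()].
#' @return list with `freqs` (a `freq_table`: matrix `p` sites x populations,
#'   site coordinates) and `truth` (a `truth_track`: the pulse windows with
#'   donor/recipient/f, plus the true frequency matrix).
#' @export
simulate_frequencies <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  set.seed(config$seed)
  coords <- site_coordinates(config)
  n <- nrow(coords)
  p_anc <- stats::runif(n, config$ancestral_freq_range[1],
                        config$ancestral_freq_range[2])
  tr <- config$population_tree
  freq <- list()
  freq[[config$root]] <- p_anc
  # rows are processed repeatedly until all parents are resolved; with a
  # valid tree a single ordered pass over a topological sort suffices
  todo <- seq_len(nrow(tr))
  while (length(todo)) {
    ready <- todo[tr$parent[todo] %in% names(freq)]
    if (!length(ready)) stop("population_tree is not a connected rooted tree")
    for (i in ready) {
      freq[[tr$child[i]]] <- bn_drift(freq[[tr$parent[i]]], tr$F[i])
    }
    todo <- setdiff(todo, ready)
  }
  p <- do.call(cbind, freq[config$leaves])
  colnames(p) <- config$leaves
  truth_windows <- list()
  for (pl in config$admixture_pulses) {
    widx <- assign_windows(coords, pl$windows)
    inside <- !is.na(widx)
    p[inside, pl$recipient] <- (1 - pl$f) * p[inside, pl$recipient] +
      pl$f * p[inside, pl$donor]
    if (nrow(pl$windows)) {
      truth_windows[[length(truth_windows) + 1L]] <-
        data.frame(pl$windows, donor = pl$donor, recipient = pl$recipient,
                   f = pl$f)
    }
  }
  tw <- if (length(truth_windows)) do.call(rbind, truth_windows) else
    data.frame(chrom = character(), start = numeric(), end = numeric(),
               donor = character(), recipient = character(), f = numeric())
  freqs <- structure(list(sites = coords, p = p,
                          populations = config$leaves),
                     class = "freq_table")
  truth <- structure(list(introgressed_windows = tw, true_freqs = p,
                          sites = coords),
                     class = "truth_track")
  list(freqs = freqs, truth = truth)
}

#' Sample diploid genotypes from population frequencies
#'
#' Each genotype is Binomial(2, p) for its site and population; missingness
#' is independent Bernoulli. Per-site QUAL, summed DP and RMS MQ covariates
#' are drawn from the configured models, and ref/alt allele pairs are drawn
#' so the expected transition:transversion ratio equals `target_ts_tv`.
#' Seeded from `config$seed + 1` so frequency simulation and genotype
#' sampling are independently reproducible substreams.
#'
#' @param freqs a `freq_table` from [simulate_frequencies()].
#' @param config the [scenario_config()] used to produce it.
#' @return list with `genotypes` (a [genotype_matrix()]) and `popmap`
#'   (a [population_map()]; group = population here, regroup as needed).
#' @export
sample_genotypes <- function(freqs, config) {
  stopifnot(inherits(freqs, "freq_table"))
  if (any(freqs$p < 0 | freqs$p > 1)) stop("frequencies must lie in [0, 1]")
  set.seed(config$seed + 1L)
  n <- nrow(freqs$sites)
  pops <- freqs$populations
  counts <- config$samples_per_population[pops]
  sample_pop <- rep(pops, counts)
  sample_ids <- unlist(lapply(pops, function(pp)
    sprintf("%s_%02d", pp, seq_len(counts[[pp]]))), use.names = FALSE)
  m <- length(sample_ids)
  pmat <- freqs$p[, sample_pop, drop = FALSE]
  g <- matrix(stats::rbinom(n * m, 2L, as.vector(pmat)), nrow = n)
  if (config$missing_rate > 0) {
    g[stats::runif(n * m) < config$missing_rate] <- NA_integer_
  }
  # allele pairs: transition with probability t/(1+t); transitions have one
  # partner, transversions two
  bases <- c("A", "C", "G", "T")
  ts_partner <- c(A = "G", G = "A", C = "T", T = "C")
  tv_partners <- list(A = c("C", "T"), G = c("C", "T"),
                      C = c("A", "G"), T = c("A", "G"))
  ref <- sample(bases, n, replace = TRUE)
  t <- config$target_ts_tv
  is_ts <- stats::runif(n) < t / (1 + t)
  pick2 <- 1L + (stats::runif(n) < 0.5)
  alt <- ifelse(is_ts, ts_partner[ref],
                mapply(function(r, k) tv_partners[[r]][k], ref, pick2))
  qm <- config$quality_model
  qual <- round(pmax(1, stats::rnorm(n, qm$qual_mean, qm$qual_sd)), 2)
  mq <- round(pmax(1, stats::rnorm(n, qm$mq_mean, qm$mq_sd)), 2)
  dp <- stats::rpois(n, config$depth_model$mean_per_sample * m)
  sites <- data.frame(chrom = freqs$sites$chrom, pos = freqs$sites$pos,
                      ref = ref, alt = unname(alt),
                      qual = qual, dp = dp, mq = mq)
  gm <- genotype_matrix(sites, g, sample_ids)
  list(genotypes = gm,
       popmap = population_map(sample_ids, sample_pop))
}

#' Default eight-population camel scenario
#'
#' A dromedary outgroup, a wild Bactrian population and six domestic
#' Bactrian populations (IRAN, KAZA, RUS as Central Asian; MG, IMG, XJ as
#' East Asian), with IRAN the earliest-splitting domestic. Branch drift
#' coefficients are calibrated so realized pairwise Weir-Cockerham Fst falls
#' in the ranges reported for the real panel: about 0.54-0.64 between the
#' dromedary and any Bactrian population, 0.27-0.31 between wild and domestic
#' Bactrians, and 0.05-0.06 between IRAN and the other domestics. Dromedary
#' admixture pulses (default proportion within the reported 1-10%) enter the
#' Central Asian populations in a deterministic subset of 100 kb windows.
#'
#' @param n_sites number of sites (default 1e5 on a 10 Mb chromosome at
#'   100 bp spacing, i.e. 100 non-overlapping 100 kb windows).
#' @param samples_per_population diploids per population.
#' @param pulse_f admixture proportion for each dromedary pulse, named by
#'   recipient (defaults within 1-10%); use `numeric(0)` or
#'   `introgressed_fraction = 0` for a pulse-free control.
#' @param introgressed_fraction fraction of 100 kb windows carrying the
#'   pulses (the same windows for every recipient; every 1/fraction-th
#'   window, so occupancy is deterministic).
#' @param window_size pulse window size in bp.
#' @param seed integer seed.
#' @return A [scenario_config()].
#' @export
make_camel_scenario <- function(n_sites = 1e5,
                                samples_per_population = 20,
                                pulse_f = c(IRAN = 0.05, KAZA = 0.05,
                                            RUS = 0.05),
                                introgressed_fraction = 0.2,
                                window_size = 1e5,
                                seed = 1) {
  tree <- data.frame(
    child  = c("drom", "bact", "wild", "dom", "IRAN", "dom2", "KAZA", "RUS",
               "east", "MG", "IMG", "XJ"),
    parent = c("root", "root", "bact", "bact", "dom", "dom", "dom2", "dom2",
               "dom2", "east", "east", "east"),
    F      = c(0.67, 0.30, 0.32, 0.20, 0.055, 0.015, 0.04, 0.04,
               0.015, 0.025, 0.025, 0.025))
  spacing <- 100
  chrom_len <- c(chr1 = n_sites * spacing)
  pulses <- list()
  if (length(pulse_f) && introgressed_fraction > 0) {
    wins <- make_windows(chrom_len, window_size)
    step <- max(1L, round(1 / introgressed_fraction))
    sel <- wins[seq(1, nrow(wins), by = step), , drop = FALSE]
    for (rec in names(pulse_f)) {
      pulses[[length(pulses) + 1L]] <-
        list(donor = "drom", recipient = rec, f = pulse_f[[rec]],
             windows = sel)
    }
  }
  scenario_config(population_tree = tree,
                  admixture_pulses = pulses,
                  n_sites = n_sites,
                  site_spacing = spacing,
                  chromosome_lengths = chrom_len,
                  samples_per_population = samples_per_population,
                  seed = seed)
}

# Species-level grouping for the camel scenario.
camel_groups <- function() {
  c(drom = "dromedary", wild = "wild",
    IRAN = "domestic", KAZA = "domestic", RUS = "domestic",
    MG = "domestic", IMG = "domestic", XJ = "domestic")
}

#' Simulate a full scenario end to end
#'
#' Convenience wrapper: frequencies, truth and genotypes in one call, with
#' the camel species-level grouping applied when the populations match the
#' default scenario.
#'
#' @param config a [scenario_config()].
#' @return list with `genotypes`, `popmap`, `freqs`, `truth`.
#' @export
simulate_scenario <- function(config) {
  sim <- simulate_frequencies(config)
  gs <- sample_genotypes(sim$freqs, config)
  grp <- camel_groups()
  if (all(gs$popmap$population %in% names(grp))) {
    gs$popmap$group <- unname(grp[gs$popmap$population])
  }
  list(genotypes = gs$genotypes, popmap = gs$popmap,
       freqs = sim$freqs, truth = sim$truth)
}

#' Write scenario outputs (VCF + population map + truth BED)
#'
#' @param genotypes a [genotype_matrix()].
#' @param popmap a [population_map()].
#' @param truth a `truth_track` (or NULL to skip the BED).
#' @param prefix output path prefix; writes `<prefix>.vcf`,
#'   `<prefix>.popmap.tsv`, `<prefix>.truth.bed`.
#' @return named character vector of the written paths, invisibly.
#' @export
write_outputs <- function(genotypes, popmap, truth, prefix) {
  paths <- c(vcf = paste0(prefix, ".vcf"),
             popmap = paste0(prefix, ".popmap.tsv"),
             bed = paste0(prefix, ".truth.bed"))
  write_vcf(genotypes, paths[["vcf"]])
  write_popmap(popmap, paths[["popmap"]])
  if (!is.null(truth)) {
    write_bed(truth$introgressed_windows, paths[["bed"]])
  } else {
    paths <- paths[c("vcf", "popmap")]
  }
  invisible(paths)
}

#' Write genomic intervals as BED (0-based half-open)
#'
#' @param intervals data.frame with columns `chrom`, `start`, `end` (extra
#'   columns are appended).
#' @param path output path.
#' @export
write_bed <- function(intervals, path) {
  df <- intervals[order(intervals$chrom, intervals$start), , drop = FALSE]
  front <- c("chrom", "start", "end")
  df <- df[, c(front, setdiff(names(df), front)), drop = FALSE]
  utils::write.table(format(df, scientific = FALSE, trim = TRUE), path,
                     sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
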