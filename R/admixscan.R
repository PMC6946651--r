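#' Four-population (ABBA-BABA) test configuration
#'
#' A quartet `(Y, Z; W, X)`: `Y` and `Z` are the sister ingroups being
#' compared (e.g. East Asian vs Central Asian domestic Bactrians), `W` their
#' outgroup within the clade (wild Bactrian) and `X` the candidate donor
#' (dromedary). Each slot may pool several populations; pooled frequencies
#' count all member alleles.
#'
#' @param Y,Z,W,X character vectors of population (or group) labels.
#' @return list of class `quartet_config`.
#' @export
quartet_config <- function(Y, Z, W, X) {
  labs <- list(Y = Y, Z = Z, W = W, X = X)
  flat <- unlist(labs)
  if (anyDuplicated(flat)) stop("quartet labels must be distinct")
  structure(labs, class = "quartet_config")
}

# Frequency matrix (sites x Y,Z,W,X) for a quartet from genotypes.
quartet_frequencies <- function(gm, popmap, quartet) {
  ft <- allele_frequencies(gm, popmap,
                           pops = list(Y = quartet$Y, Z = quartet$Z,
                                       W = quartet$W, X = quartet$X))
  ft$p
}

# Accept a freq_table, matrix or data.frame; return the frequency matrix
# restricted to `cols` (NULL = as is).
freq_matrix <- function(freqs, cols = NULL) {
  p <- if (inherits(freqs, "freq_table")) freqs$p else as.matrix(freqs)
  if (!is.null(cols)) {
    miss <- setdiff(cols, colnames(p))
    if (length(miss)) stop("frequency table lacks column(s): ",
                           paste(miss, collapse = ", "))
    p <- p[, cols, drop = FALSE]
  }
  p
}

# Per-site terms of the D and f_d ratios for frequency columns Y,Z,W,X.
# num: shared-derived excess; den_d: D denominator; den_pos / den_neg: f_d
# denominators for the D > 0 and D < 0 branches.
abba_site_terms <- function(pY, pZ, pW, pX) {
  list(num = (pY - pZ) * (pW - pX),
       den_d = (pY + pZ - 2 * pY * pZ) * (pW + pX - 2 * pW * pX),
       den_pos = pmax((pX - pY) * (pX - pW), (pZ - pY) * (pZ - pW)),
       den_neg = pmax((pX - pZ) * (pX - pW), (pY - pZ) * (pY - pW)))
}

# f_d from term sums; branch chosen by the sign of D on the same sums.
fd_from_sums <- function(s_num, s_den_d, s_den_pos, s_den_neg) {
  if (s_den_d == 0) return(NA_real_)
  d <- s_num / s_den_d
  if (d == 0) return(0)
  den <- if (d > 0) s_den_pos else s_den_neg
  if (den == 0) return(NA_real_)
  s_num / den
}

#' Patterson's D statistic
#'
#' `D = E[(p_Y - p_Z)(p_W - p_X)] / E[(p_Y + p_Z - 2 p_Y p_Z)(p_W + p_X -
#' 2 p_W p_X)]`, expectations taken as means over the used sites. Sites with
#' any undefined frequency are skipped; a zero denominator yields `NA`.
#'
#' @param freqs a `freq_table` or a matrix/data.frame of per-site
#'   frequencies containing the quartet's columns.
#' @param quartet column names in `(Y, Z, W, X)` order (default
#'   `c("Y","Z","W","X")`).
#' @param sites optional index restricting the used sites.
#' @return D (numeric scalar, `NA` when undefined).
#' @export
patterson_d <- function(freqs, quartet = c("Y", "Z", "W", "X"),
                        sites = NULL) {
  p <- freq_matrix(freqs, quartet)
  if (!is.null(sites)) p <- p[sites, , drop = FALSE]
  use <- stats::complete.cases(p)
  if (!any(use)) return(NA_real_)
  tm <- abba_site_terms(p[use, 1], p[use, 2], p[use, 3], p[use, 4])
  if (sum(tm$den_d) == 0) return(NA_real_)
  sum(tm$num) / sum(tm$den_d)
}

#' The window-local f_d introgression statistic
#'
#' A bounded, window-robust variant of the D-based admixture-fraction
#' estimator: the numerator is the same shared-derived excess as D, while
#' the denominator replaces the recipient by the candidate donor, per site
#' taking the larger of the two donor substitutions. The branch (which of
#' `Z` / `Y` is treated as recipient) follows the sign of D on the same
#' sites; `D = 0` gives `f_d = 0` by continuity.
#'
#' @inheritParams patterson_d
#' @return f_d (numeric scalar, `NA` when the denominator is degenerate).
#' @export
f_d_statistic <- function(freqs, quartet = c("Y", "Z", "W", "X"),
                          sites = NULL) {
  p <- freq_matrix(freqs, quartet)
  if (!is.null(sites)) p <- p[sites, , drop = FALSE]
  use <- stats::complete.cases(p)
  if (!any(use)) return(NA_real_)
  tm <- abba_site_terms(p[use, 1], p[use, 2], p[use, 3], p[use, 4])
  fd_from_sums(sum(tm$num), sum(tm$den_d), sum(tm$den_pos), sum(tm$den_neg))
}

#' Delete-one block jackknife Z-score
#'
#' Pseudo-estimates are the statistic recomputed with one block removed at a
#' time; `Z = mean(pseudo) / sqrt(var(pseudo) * n)` with `n` the number of
#' blocks and `var` the sample variance. `n_convention = "n-1"` switches to
#' the textbook delete-one scaling `var * (n - 1)`. Zero variance yields a
#' signed infinite flag, or 0 when every pseudo-value is 0.
#'
#' @param stat_fn function(site indices) -> statistic value.
#' @param blocks list of integer site-index vectors (>= 2 blocks).
#' @param n_convention `"n"` (`var * n`) or `"n-1"` (`var * (n - 1)`).
#' @return list with `z`, `pseudovalues`, `mean`, `var`, `n_blocks`.
#' @export
block_jackknife_z <- function(stat_fn, blocks,
                              n_convention = c("n", "n-1")) {
  n_convention <- match.arg(n_convention)
  nb <- length(blocks)
  if (nb < 2) stop("block jackknife needs at least 2 blocks")
  all_idx <- unlist(blocks, use.names = FALSE)
  pseudo <- vapply(seq_len(nb), function(i) {
    stat_fn(setdiff(all_idx, blocks[[i]]))
  }, numeric(1))
  m <- mean(pseudo)
  v <- stats::var(pseudo)
  scale <- if (n_convention == "n") nb else nb - 1
  z <- if (is.na(v)) {
    NA_real_
  } else if (v == 0) {
    if (m == 0) 0 else sign(m) * Inf
  } else {
    m / sqrt(v * scale)
  }
  list(z = z, pseudovalues = pseudo, mean = m, var = v, n_blocks = nb)
}

#' Windowed f_d introgression scan
#'
#' For each non-overlapping genomic window: Patterson's D and f_d over the
#' window's usable sites, and a Z-score for f_d from a delete-one jackknife
#' over sub-blocks within the window. Classification: `Z > z_threshold` ->
#' `"into_Z"` (gene flow between X and the Z side), `Z < -z_threshold` ->
#' `"into_Y"`, otherwise `"none"`; windows with a degenerate denominator or
#' fewer than two usable blocks are `"undefined"`.
#'
#' @param gm a [genotype_matrix()].
#' @param popmap a [population_map()].
#' @param quartet a [quartet_config()].
#' @param window_size scan window in bp (default 100 kb).
#' @param block_size jackknife block in bp (default 10 kb).
#' @param z_threshold significance level on the Z-score (default 2).
#' @param chrom_lengths optional named lengths; inferred from the site
#'   positions when NULL.
#' @param n_convention jackknife scaling, see [block_jackknife_z()].
#' @return data.frame with one row per window: `chrom`, `start`, `end`,
#'   `D`, `f_d`, `z`, `n_sites`, `n_blocks`, `classification`.
#' @export
introgression_scan <- function(gm, popmap, quartet, window_size = 1e5,
                               block_size = 1e4, z_threshold = 2,
                               chrom_lengths = NULL,
                               n_convention = c("n", "n-1")) {
  n_convention <- match.arg(n_convention)
  if (window_size < block_size) {
    stop("window_size must be at least block_size")
  }
  if (is.null(chrom_lengths)) {
    chrom_lengths <- infer_chrom_lengths(gm$sites, window_size)
  }
  windows <- make_windows(chrom_lengths, window_size)
  p <- quartet_frequencies(gm, popmap, quartet)
  use <- stats::complete.cases(p)
  tm <- abba_site_terms(p[, 1], p[, 2], p[, 3], p[, 4])
  wi <- assign_windows(gm$sites, windows)
  block_id <- floor((gm$sites$pos - 1) / block_size)
  out <- windows
  out$D <- NA_real_; out$f_d <- NA_real_; out$z <- NA_real_
  out$n_sites <- 0L; out$n_blocks <- 0L
  out$classification <- "undefined"
  nb_scale <- function(nb) if (n_convention == "n") nb else nb - 1
  for (w in seq_len(nrow(windows))) {
    idx <- which(wi == w & use)
    out$n_sites[w] <- length(idx)
    if (!length(idx)) next
    s_num <- rowsum(tm$num[idx], block_id[idx])
    s_dd <- rowsum(tm$den_d[idx], block_id[idx])
    s_dp <- rowsum(tm$den_pos[idx], block_id[idx])
    s_dn <- rowsum(tm$den_neg[idx], block_id[idx])
    t_num <- sum(s_num); t_dd <- sum(s_dd)
    t_dp <- sum(s_dp); t_dn <- sum(s_dn)
    nb <- nrow(s_num)
    out$n_blocks[w] <- nb
    if (t_dd != 0) out$D[w] <- t_num / t_dd
    out$f_d[w] <- fd_from_sums(t_num, t_dd, t_dp, t_dn)
    if (is.na(out$f_d[w]) || nb < 2) next
    pseudo <- vapply(seq_len(nb), function(i) {
      fd_from_sums(t_num - s_num[i], t_dd - s_dd[i],
                   t_dp - s_dp[i], t_dn - s_dn[i])
    }, numeric(1))
    if (anyNA(pseudo)) next
    m <- mean(pseudo); v <- stats::var(pseudo)
    z <- if (v == 0) {
      if (m == 0) 0 else sign(m) * Inf
    } else m / sqrt(v * nb_scale(nb))
    out$z[w] <- z
    out$classification[w] <-
      if (z > z_threshold) "into_Z"
      else if (z < -z_threshold) "into_Y"
      else "none"
  }
  out
}

#' Mask introgressed windows
#'
#' Removes every site inside scan windows with `|Z| > z_threshold` (both
#' directions by default) and returns the complement plus a BED-style table
#' of the removed windows.
#'
#' @param gm a [genotype_matrix()].
#' @param scan output of [introgression_scan()] on the same coordinates.
#' @param z_threshold threshold on `|Z|` (default 2).
#' @param directions `"both"` to remove `|Z| >` threshold, `"into_Z"` or
#'   `"into_Y"` to remove one direction only.
#' @return list with `genotypes` (masked matrix) and `removed` (data.frame
#'   of removed windows with their scan values).
#' @export
mask_introgressed <- function(gm, scan, z_threshold = 2,
                              directions = c("both", "into_Z", "into_Y")) {
  directions <- match.arg(directions)
  z <- scan$z
  hit <- switch(directions,
                both = !is.na(z) & abs(z) > z_threshold,
                into_Z = !is.na(z) & z > z_threshold,
                into_Y = !is.na(z) & z < -z_threshold)
  removed <- scan[hit, , drop = FALSE]
  if (!nrow(removed)) return(list(genotypes = gm, removed = removed))
  wi <- assign_windows(gm$sites, removed)
  list(genotypes = subset_sites(gm, is.na(wi)), removed = removed)
}

# Consecutive-SNP jackknife blocks for F3/F4 (TreeMix-style -k blocks).
snp_blocks <- function(n_sites, block_size) {
  if (n_sites < 1) return(list())
  split(seq_len(n_sites), (seq_len(n_sites) - 1) %/% block_size)
}

#' F3 admixture test
#'
#' `F3(Z; X, Y) = mean over sites of (p_Z - p_X)(p_Z - p_Y)`, standardized
#' to a Z-score with a jackknife over blocks of consecutive SNPs. A strongly
#' negative score flags `Z` as a mixture of `X` and `Y`.
#'
#' @param freqs a `freq_table` or frequency matrix.
#' @param Z,X,Y column labels (focal population first).
#' @param block_size SNPs per jackknife block (default 500).
#' @param z_flag admixture is flagged when the Z-score is below this
#'   (default -3).
#' @param n_convention see [block_jackknife_z()].
#' @return list of class `admixture_test`: `test`, `labels`, `value`, `z`,
#'   `n_blocks`, `n_sites`, `admixture_flag`.
#' @export
f3_test <- function(freqs, Z, X, Y, block_size = 500, z_flag = -3,
                    n_convention = c("n", "n-1")) {
  p <- freq_matrix(freqs, c(Z, X, Y))
  p <- p[stats::complete.cases(p), , drop = FALSE]
  term <- (p[, 1] - p[, 2]) * (p[, 1] - p[, 3])
  blocks <- snp_blocks(length(term), block_size)
  if (length(blocks) < 2) stop("need at least 2 SNP blocks for the jackknife")
  jk <- block_jackknife_z(function(i) mean(term[i]), blocks,
                          n_convention = match.arg(n_convention))
  structure(list(test = "F3", labels = c(Z = Z, X = X, Y = Y),
                 value = mean(term), z = jk$z, n_blocks = jk$n_blocks,
                 n_sites = length(term),
                 admixture_flag = !is.na(jk$z) && jk$z < z_flag),
            class = "admixture_test")
}

#' F4 admixture test
#'
#' `F4(Y, Z; W, X) = mean over sites of (p_Y - p_Z)(p_W - p_X)`, with a
#' SNP-block jackknife Z-score. With `W` an outgroup of `Y` and `Z`, a
#' significantly negative score indicates `Y` shares more ancestry with `X`;
#' positive, `Z` does.
#'
#' @inheritParams f3_test
#' @param Y,Z,W,X column labels.
#' @return list of class `admixture_test`.
#' @export
f4_test <- function(freqs, Y, Z, W, X, block_size = 500,
                    n_convention = c("n", "n-1")) {
  p <- freq_matrix(freqs, c(Y, Z, W, X))
  p <- p[stats::complete.cases(p), , drop = FALSE]
  term <- (p[, 1] - p[, 2]) * (p[, 3] - p[, 4])
  blocks <- snp_blocks(length(term), block_size)
  if (length(blocks) < 2) stop("need at least 2 SNP blocks for the jackknife")
  jk <- block_jackknife_z(function(i) mean(term[i]), blocks,
                          n_convention = match.arg(n_convention))
  structure(list(test = "F4", labels = c(Y = Y, Z = Z, W = W, X = X),
                 value = mean(term), z = jk$z, n_blocks = jk$n_blocks,
                 n_sites = length(term)),
            class = "admixture_test")
}

#' @export
print.admixture_test <- function(x, ...) {
  cat(sprintf("%s(%s): value = %.6g, jackknife Z = %.3f (%d blocks, %d sites)\n",
              x$test, paste(x$labels, collapse = ", "), x$value, x$z,
              x$n_blocks, x$n_sites))
  invisible(x)
}

#' Total migration rate of a migration band
#'
#' `M = m * tau_m`: the mutation-scaled per-generation migration rate times
#' the mutation-scaled time span of the band.
#'
#' @param m mutation-scaled migration rate per generation (>= 0).
#' @param tau_m mutation-scaled time span (>= 0).
#' @return M (numeric).
#' @export
total_migration_rate <- function(m, tau_m) {
  if (any(m < 0) || any(tau_m < 0)) stop("m and tau_m must be nonnegative")
  m * tau_m
}
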