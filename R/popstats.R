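#' Per-population allele frequencies
#'
#' For each site and population: alternate-allele frequency
#' `p = alt count / non-missing allele count` and the non-missing allele
#' count `n`. Cells with `n = 0` have `p = NA`. Labels may be population or
#' group names; a label set pools all its samples' alleles.
#'
#' @param gm a [genotype_matrix()].
#' @param popmap a [population_map()].
#' @param pops labels to tabulate (default: every population). To pool
#'   several populations under one column, pass a named list, e.g.
#'   `list(east = c("MG", "XJ"), drom = "drom")`.
#' @return A `freq_table`: list with `p` and `n` matrices (sites x labels)
#'   and the site coordinates.
#' @export
allele_frequencies <- function(gm, popmap, pops = NULL) {
  if (is.null(pops)) pops <- unique(popmap$population)
  if (!is.list(pops)) pops <- stats::setNames(as.list(pops), pops)
  if (is.null(names(pops))) names(pops) <- vapply(pops, paste,
                                                  character(1),
                                                  collapse = "+")
  p <- matrix(NA_real_, nrow(gm$geno), length(pops),
              dimnames = list(NULL, names(pops)))
  nmat <- matrix(0L, nrow(gm$geno), length(pops),
                 dimnames = list(NULL, names(pops)))
  for (j in seq_along(pops)) {
    ids <- samples_for(popmap, pops[[j]])
    sub <- gm$geno[, gm$samples %in% ids, drop = FALSE]
    ac <- rowSums(sub, na.rm = TRUE)
    an <- 2L * as.integer(rowSums(!is.na(sub)))
    nmat[, j] <- an
    p[, j] <- ifelse(an > 0, ac / an, NA_real_)
  }
  structure(list(sites = gm$sites[, c("chrom", "pos")], p = p, n = nmat,
                 populations = names(pops)),
            class = "freq_table")
}

# Per-site within-population counts used by pi/theta: x = alt alleles,
# n = non-missing alleles.
pop_site_counts <- function(gm, popmap, pop) {
  ids <- samples_for(popmap, pop)
  sub <- gm$geno[, gm$samples %in% ids, drop = FALSE]
  list(x = rowSums(sub, na.rm = TRUE),
       n = 2L * rowSums(!is.na(sub)))
}

#' Windowed nucleotide diversity (pi)
#'
#' Per site, the expected heterozygosity between two sampled alleles,
#' `2 x (n - x) / (n (n - 1))` with `x` alternate alleles out of `n`
#' non-missing; the window value sums sites and divides by the window span
#' in bp (monomorphic and absent sites contribute zero). Sites with fewer
#' than two called alleles are skipped.
#'
#' @param gm a [genotype_matrix()].
#' @param popmap a [population_map()].
#' @param pop population (or group) label.
#' @param windows data.frame `chrom`, `start`, `end`; default: 10 kb tiling
#'   of the inferred chromosome extents.
#' @param window_size used when `windows` is NULL.
#' @return data.frame `chrom`, `start`, `end`, `stat`, `value`, `n_sites`.
#' @export
nucleotide_diversity <- function(gm, popmap, pop, windows = NULL,
                                 window_size = 1e4) {
  if (is.null(windows)) {
    windows <- make_windows(infer_chrom_lengths(gm$sites, window_size),
                            window_size)
  }
  cs <- pop_site_counts(gm, popmap, pop)
  use <- cs$n >= 2
  pi_site <- numeric(nrow(gm$sites))
  pi_site[use] <- 2 * cs$x[use] * (cs$n[use] - cs$x[use]) /
    (cs$n[use] * (cs$n[use] - 1))
  wi <- assign_windows(gm$sites, windows)
  val <- rep(0, nrow(windows))
  cnt <- rep(0L, nrow(windows))
  ok <- !is.na(wi) & use
  if (any(ok)) {
    agg <- rowsum(pi_site[ok], wi[ok])
    val[as.integer(rownames(agg))] <- agg[, 1]
    tb <- table(wi[ok])
    cnt[as.integer(names(tb))] <- as.integer(tb)
  }
  data.frame(windows, stat = "pi",
             value = val / (windows$end - windows$start),
             n_sites = cnt)
}

#' Windowed Watterson's theta
#'
#' Window value `S / a_n / L`: `S` segregating sites within the population,
#' `a_n` the harmonic number `sum(1/1..(n-1))` with `n` the modal non-missing
#' allele count across the window's usable sites, `L` the window span in bp.
#' Windows with no usable site get `NA`.
#'
#' @inheritParams nucleotide_diversity
#' @return data.frame as [nucleotide_diversity()] with `stat = "theta_w"`.
#' @export
watterson_theta <- function(gm, popmap, pop, windows = NULL,
                            window_size = 1e4) {
  if (is.null(windows)) {
    windows <- make_windows(infer_chrom_lengths(gm$sites, window_size),
                            window_size)
  }
  cs <- pop_site_counts(gm, popmap, pop)
  use <- cs$n >= 2
  seg <- use & cs$x > 0 & cs$x < cs$n
  wi <- assign_windows(gm$sites, windows)
  val <- rep(NA_real_, nrow(windows))
  cnt <- rep(0L, nrow(windows))
  for (w in unique(wi[!is.na(wi)])) {
    in_w <- which(wi == w & use)
    cnt[w] <- length(in_w)
    if (!length(in_w)) next
    nn <- cs$n[in_w]
    tb <- table(nn)
    n_modal <- as.integer(names(tb)[which.max(tb)])
    a <- sum(1 / seq_len(n_modal - 1))
    val[w] <- sum(seg[in_w]) / a / (windows$end[w] - windows$start[w])
  }
  data.frame(windows, stat = "theta_w", value = val, n_sites = cnt)
}

# Per-site Weir & Cockerham (1984) variance components for two populations.
# Inputs are per-site vectors: sample sizes (diploids), alt frequencies and
# observed heterozygote proportions. Returns a (among populations) and the
# full denominator a + b + c; sites are expected pre-screened for n >= 2.
wc_components <- function(nA, pA, hA, nB, pB, hB) {
  r <- 2
  nbar <- (nA + nB) / 2
  nc <- (r * nbar - (nA^2 + nB^2) / (r * nbar)) / (r - 1)
  pbar <- (nA * pA + nB * pB) / (r * nbar)
  s2 <- (nA * (pA - pbar)^2 + nB * (pB - pbar)^2) / ((r - 1) * nbar)
  hbar <- (nA * hA + nB * hB) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  c <- hbar / 2
  list(a = a, abc = a + b + c)
}

# Per-site n (diploids), p and het proportion for one population label set.
pop_site_stats <- function(gm, popmap, pop) {
  ids <- samples_for(popmap, pop)
  sub <- gm$geno[, gm$samples %in% ids, drop = FALSE]
  n <- rowSums(!is.na(sub))
  ac <- rowSums(sub, na.rm = TRUE)
  het <- rowSums(sub == 1L, na.rm = TRUE)
  list(n = n, p = ifelse(n > 0, ac / (2 * n), NA_real_),
       h = ifelse(n > 0, het / n, NA_real_))
}

#' Windowed Weir-Cockerham Fst between two populations
#'
#' Per usable site (>= 2 non-missing diploids in each population) the
#' Weir & Cockerham (1984) variance components are computed from observed
#' sample sizes, frequencies and heterozygote proportions; window and
#' overall estimates are ratio-of-sums `sum(a) / sum(a + b + c)`. Raw
#' estimates may be slightly negative. Sites contributing a zero denominator
#' add nothing.
#'
#' @param gm a [genotype_matrix()].
#' @param popmap a [population_map()].
#' @param popA,popB population (or group) labels.
#' @param windows data.frame of windows, or NULL for the overall estimate
#'   only.
#' @return list with `overall` (numeric) and `windows` (data.frame with
#'   `value` and `n_sites`; NA where a window has no usable site).
#' @export
weir_fst <- function(gm, popmap, popA, popB, windows = NULL) {
  sa <- pop_site_stats(gm, popmap, popA)
  sb <- pop_site_stats(gm, popmap, popB)
  use <- sa$n >= 2 & sb$n >= 2
  comp <- wc_components(sa$n[use], sa$p[use], sa$h[use],
                        sb$n[use], sb$p[use], sb$h[use])
  overall <- if (sum(comp$abc) == 0) NA_real_ else
    sum(comp$a) / sum(comp$abc)
  wdf <- NULL
  if (!is.null(windows)) {
    wi <- assign_windows(gm$sites, windows)[use]
    val <- rep(NA_real_, nrow(windows))
    cnt <- rep(0L, nrow(windows))
    ok <- !is.na(wi)
    if (any(ok)) {
      sa_w <- rowsum(comp$a[ok], wi[ok])
      sd_w <- rowsum(comp$abc[ok], wi[ok])
      j <- as.integer(rownames(sa_w))
      val[j] <- ifelse(sd_w[, 1] == 0, NA_real_, sa_w[, 1] / sd_w[, 1])
      tb <- table(wi[ok])
      cnt[as.integer(names(tb))] <- as.integer(tb)
    }
    wdf <- data.frame(windows, stat = "fst", value = val, n_sites = cnt)
  }
  list(overall = overall, windows = wdf)
}

#' Identity-by-state distance matrix between individuals
#'
#' `d(i, j)` is the mean of `|g_i - g_j| / 2` over sites where both
#' genotypes are called. A pair with no commonly called site is an error.
#'
#' @param gm a [genotype_matrix()].
#' @return symmetric matrix with zero diagonal, labelled by sample id.
#' @export
ibs_distance_matrix <- function(gm) {
  G <- gm$geno
  m <- ncol(G)
  d <- matrix(0, m, m, dimnames = list(gm$samples, gm$samples))
  for (j in seq_len(m)) {
    diff <- abs(G - G[, j]) / 2
    cm <- colMeans(diff, na.rm = TRUE)
    none <- colSums(!is.na(diff)) == 0
    if (any(none & seq_len(m) != j)) {
      bad <- gm$samples[which(none & seq_len(m) != j)[1]]
      stop("no commonly called site for pair ", gm$samples[j], " / ", bad)
    }
    d[, j] <- cm
  }
  d[cbind(seq_len(m), seq_len(m))] <- 0
  (d + t(d)) / 2
}

#' Classical (Torgerson) multidimensional scaling
#'
#' Double-centers `-D^2 / 2` and takes the top-`k` non-negative eigenpairs;
#' coordinates are eigenvectors scaled by the square root of their
#' eigenvalues, axes ordered by eigenvalue. Sign convention: the first
#' nonzero loading of each axis is positive. Axes with non-positive
#' eigenvalues are dropped with a warning.
#'
#' @param d symmetric distance matrix.
#' @param k number of axes requested (default 4).
#' @return list with `points` (n x k' coordinates) and `eig` (all
#'   eigenvalues).
#' @export
classical_mds <- function(d, k = 4) {
  d <- as.matrix(d)
  kk <- min(k, nrow(d) - 1)
  fit <- suppressWarnings(stats::cmdscale(d, k = kk, eig = TRUE))
  tol <- 1e-9 * max(abs(fit$eig), 1)
  eig_k <- fit$eig[seq_len(kk)]
  n_pos <- sum(eig_k > tol)
  n_zero <- sum(abs(eig_k) <= tol)
  n_neg <- kk - n_pos - n_zero
  if (n_neg > 0) {
    warning("dropping ", n_neg, " axis/axes with negative eigenvalue")
  }
  pts <- fit$points
  if (is.null(pts)) pts <- matrix(0, nrow(d), 0)
  pts <- pts[, seq_len(min(n_pos, ncol(pts))), drop = FALSE]
  # zero-eigenvalue axes carry zero coordinates
  if (n_zero > 0) {
    pts <- cbind(pts, matrix(0, nrow(d), n_zero))
  }
  rownames(pts) <- rownames(d)
  for (j in seq_len(ncol(pts))) {
    nz <- which(abs(pts[, j]) > 1e-12)
    if (length(nz) && pts[nz[1], j] < 0) pts[, j] <- -pts[, j]
  }
  list(points = pts, eig = fit$eig)
}
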