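# Independent naive oracles, written as literal per-site loops so they share
# no code path with the package implementations they check.

# Patterson's D: per-site loop over a frequency data.frame with columns
# Y, Z, W, X.
naive_d <- function(fr) {
  num <- 0; den <- 0
  for (i in seq_len(nrow(fr))) {
    y <- fr$Y[i]; z <- fr$Z[i]; w <- fr$W[i]; x <- fr$X[i]
    if (anyNA(c(y, z, w, x))) next
    num <- num + (y - z) * (w - x)
    den <- den + (y + z - 2 * y * z) * (w + x - 2 * w * x)
  }
  if (den == 0) NA_real_ else num / den
}

naive_fd <- function(fr) {
  d <- naive_d(fr)
  if (is.na(d)) return(NA_real_)
  num <- 0; den <- 0
  for (i in seq_len(nrow(fr))) {
    y <- fr$Y[i]; z <- fr$Z[i]; w <- fr$W[i]; x <- fr$X[i]
    if (anyNA(c(y, z, w, x))) next
    num <- num + (y - z) * (w - x)
    den <- den + if (d > 0) {
      max((x - y) * (x - w), (z - y) * (z - w))
    } else {
      max((x - z) * (x - w), (y - z) * (y - w))
    }
  }
  if (d == 0) return(0)
  if (den == 0) NA_real_ else num / den
}

naive_f3 <- function(pz, px, py) {
  vals <- numeric(0)
  for (i in seq_along(pz)) {
    if (anyNA(c(pz[i], px[i], py[i]))) next
    vals <- c(vals, (pz[i] - px[i]) * (pz[i] - py[i]))
  }
  mean(vals)
}

naive_f4 <- function(py, pz, pw, px) {
  vals <- numeric(0)
  for (i in seq_along(py)) {
    if (anyNA(c(py[i], pz[i], pw[i], px[i]))) next
    vals <- c(vals, (py[i] - pz[i]) * (pw[i] - px[i]))
  }
  mean(vals)
}

# Nucleotide diversity by brute-force enumeration of allele pairs: for each
# site list the called alleles and average mismatches over all pairs, then
# divide the window sum by the window span.
naive_pi_window <- function(geno_rows, span) {
  tot <- 0
  for (i in seq_len(nrow(geno_rows))) {
    g <- geno_rows[i, ]
    g <- g[!is.na(g)]
    alleles <- unlist(lapply(g, function(v) c(as.integer(v >= 1),
                                              as.integer(v == 2))))
    n <- length(alleles)
    if (n < 2) next
    mism <- 0; npair <- 0
    for (a in seq_len(n - 1)) {
      for (b in (a + 1):n) {
        mism <- mism + abs(alleles[a] - alleles[b])
        npair <- npair + 1
      }
    }
    tot <- tot + mism / npair
  }
  tot / span
}

# Weir & Cockerham (1984) theta for two populations, coded scalar-by-scalar
# from the published component formulas (r = 2).
naive_wc_fst <- function(gA, gB) {
  sum_a <- 0; sum_abc <- 0
  for (i in seq_len(nrow(gA))) {
    a_row <- gA[i, ][!is.na(gA[i, ])]
    b_row <- gB[i, ][!is.na(gB[i, ])]
    n1 <- length(a_row); n2 <- length(b_row)
    if (n1 < 2 || n2 < 2) next
    p1 <- sum(a_row) / (2 * n1); p2 <- sum(b_row) / (2 * n2)
    h1 <- mean(a_row == 1); h2 <- mean(b_row == 1)
    r <- 2
    nbar <- (n1 + n2) / r
    nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
    pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
    s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
    hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
    a <- nbar / nc * (s2 - 1 / (nbar - 1) *
                        (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4))
    b <- nbar / (nbar - 1) *
      (pbar * (1 - pbar) - (r - 1) / r * s2 -
         (2 * nbar - 1) / (4 * nbar) * hbar)
    cc <- hbar / 2
    sum_a <- sum_a + a
    sum_abc <- sum_abc + a + b + cc
  }
  if (sum_abc == 0) NA_real_ else sum_a / sum_abc
}

# Watterson's theta for one window, from first principles.
naive_theta_window <- function(geno_rows, span) {
  ns <- apply(geno_rows, 1, function(g) 2 * sum(!is.na(g)))
  xs <- apply(geno_rows, 1, function(g) sum(g, na.rm = TRUE))
  use <- ns >= 2
  if (!any(use)) return(NA_real_)
  n_modal <- as.integer(names(sort(table(ns[use]), decreasing = TRUE))[1])
  s <- sum(use & xs > 0 & xs < ns)
  s / sum(1 / seq_len(n_modal - 1)) / span
}

# Small random genotype matrix with plausible metadata.
random_gm <- function(n_sites, n_samples, miss = 0.1, seed = 1) {
  set.seed(seed)
  p <- runif(n_sites, 0.05, 0.95)
  g <- matrix(rbinom(n_sites * n_samples, 2, rep(p, n_samples)),
              nrow = n_sites)
  g[runif(length(g)) < miss] <- NA_integer_
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n_sites, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), character(1))
  sites <- data.frame(chrom = "chr1", pos = seq_len(n_sites) * 10,
                      ref = ref, alt = unname(alt),
                      qual = runif(n_sites, 30, 90),
                      dp = rpois(n_sites, 400),
                      mq = runif(n_sites, 20, 60))
  genotype_matrix(sites, g, sprintf("s%02d", seq_len(n_samples)))
}

# Genotype matrix built directly from a dosage matrix (sites x samples).
gm_from_geno <- function(g, chrom = "chr1", pos = NULL,
                         samples = NULL) {
  g <- as.matrix(g)
  if (is.null(pos)) pos <- seq_len(nrow(g)) * 100
  if (is.null(samples)) samples <- sprintf("s%02d", seq_len(ncol(g)))
  sites <- data.frame(chrom = chrom, pos = pos,
                      ref = "A", alt = "G",
                      qual = 50, dp = 300, mq = 40)
  genotype_matrix(sites, g, samples)
}

# Bipartition support lookup: support value of the split separating `tips`
# from the rest of the tree (either orientation), NA when absent.
split_support <- function(bs_tree, support, tips) {
  parts <- ape::prop.part(bs_tree)
  labs <- attr(parts, "labels")
  target <- sort(tips)
  other <- sort(setdiff(labs, tips))
  for (i in seq_along(parts)) {
    got <- sort(labs[parts[[i]]])
    if (identical(got, target) || identical(got, other)) return(support[i])
  }
  NA_real_
}

random_quartet_freqs <- function(n, seed) {
  set.seed(seed)
  data.frame(Y = runif(n), Z = runif(n), W = runif(n), X = runif(n))
}

# 4-record toy for the filter rules over 100 diploids: one clean survivor
# (QUAL 50, DP 300, MAF ~.05, 10% missing, MQ 40, biallelic), one QUAL
# failure, one triallelic, one rare-allele (MAF .005) failure.
toy_filter_gm <- function() {
  m <- 100
  r1 <- c(rep(1, 9), rep(NA, 10), rep(0, m - 19))  # MAF 9/180, 10% missing
  r2 <- c(rep(1, 10), rep(0, m - 10))
  r3 <- c(rep(1, 10), rep(0, m - 10))
  r4 <- c(1, rep(0, m - 1))                        # MAF 1/200 = 0.005
  g <- rbind(r1, r2, r3, r4)
  sites <- data.frame(chrom = "chr1", pos = c(100, 200, 300, 400),
                      ref = "A",
                      alt = c("G", "G", "G,T", "G"),
                      qual = c(50, 30, 50, 50),
                      dp = c(300, 300, 300, 300),
                      mq = c(40, 40, 40, 40))
  genotype_matrix(sites, g, sprintf("s%03d", 1:m))
}

# Shared quartet for the camel scans.
camel_quartet <- function() {
  quartet_config(Y = c("MG", "IMG", "XJ"), Z = c("IRAN", "KAZA", "RUS"),
                 W = "wild", X = "drom")
}

truth_window_flags <- function(scan, truth) {
  tw <- unique(truth$introgressed_windows[, c("chrom", "start", "end")])
  paste(scan$chrom, scan$start) %in% paste(tw$chrom, tw$start)
}
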