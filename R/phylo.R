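# Per-pair, per-window Weir-Cockerham sums (numerator a and denominator
# a+b+c), computed once so bootstrap replicates only re-average windows.
# Returns list(pairs, windows, A, D): A and D are windows x pairs matrices.
fst_window_sums <- function(gm, popmap, pops, windows) {
  stats_by_pop <- lapply(pops, function(p) pop_site_stats(gm, popmap, p))
  names(stats_by_pop) <- pops
  counts <- table(factor(popmap$population, levels = pops))
  if (any(counts < 2)) {
    stop("population(s) with < 2 samples: ",
         paste(names(counts)[counts < 2], collapse = ", "))
  }
  pairs <- utils::combn(pops, 2)
  wi <- assign_windows(gm$sites, windows)
  nw <- nrow(windows)
  A <- matrix(0, nw, ncol(pairs))
  D <- matrix(0, nw, ncol(pairs))
  colnames(A) <- colnames(D) <- paste(pairs[1, ], pairs[2, ], sep = "|")
  for (k in seq_len(ncol(pairs))) {
    sa <- stats_by_pop[[pairs[1, k]]]
    sb <- stats_by_pop[[pairs[2, k]]]
    use <- sa$n >= 2 & sb$n >= 2 & !is.na(wi)
    comp <- wc_components(sa$n[use], sa$p[use], sa$h[use],
                          sb$n[use], sb$p[use], sb$h[use])
    aa <- rowsum(comp$a, wi[use])
    dd <- rowsum(comp$abc, wi[use])
    j <- as.integer(rownames(aa))
    A[j, k] <- aa[, 1]
    D[j, k] <- dd[, 1]
  }
  list(pairs = pairs, windows = windows, A = A, D = D)
}

# Population distance matrix from window sums over a window subset:
# per pair, mean over usable windows of the within-window ratio-of-sums,
# floored at 0 for distance use.
dist_from_sums <- function(ws, widx = NULL) {
  if (is.null(widx)) widx <- seq_len(nrow(ws$A))
  pops <- unique(as.vector(ws$pairs))
  d <- matrix(0, length(pops), length(pops), dimnames = list(pops, pops))
  for (k in seq_len(ncol(ws$pairs))) {
    a <- ws$A[widx, k]
    den <- ws$D[widx, k]
    ok <- den != 0
    val <- if (any(ok)) max(mean(a[ok] / den[ok]), 0) else NA_real_
    d[ws$pairs[1, k], ws$pairs[2, k]] <- val
    d[ws$pairs[2, k], ws$pairs[1, k]] <- val
  }
  d
}

#' Fst-based population distance matrix
#'
#' Pairwise population distance measured as the average windowed
#' Weir-Cockerham Fst (ratio-of-sums within each window, mean over windows),
#' floored at 0.
#'
#' @param gm a [genotype_matrix()].
#' @param popmap a [population_map()].
#' @param windows data.frame of windows; default 10 kb tiling.
#' @param window_size used when `windows` is NULL.
#' @return symmetric labelled distance matrix.
#' @export
fst_distance_matrix <- function(gm, popmap, windows = NULL,
                                window_size = 1e4) {
  if (is.null(windows)) {
    windows <- make_windows(infer_chrom_lengths(gm$sites, window_size),
                            window_size)
  }
  pops <- unique(popmap$population)
  if (length(pops) < 2) stop("need at least 2 populations")
  ws <- fst_window_sums(gm, popmap, pops, windows)
  dist_from_sums(ws)
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei neighbor joining (via ape), with negative branch lengths
#' clamped to zero with a warning. Exact on additive matrices.
#'
#' @param d symmetric distance matrix with >= 3 labels.
#' @return an unrooted `phylo` tree.
#' @export
neighbor_joining <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) < 3) stop("neighbor joining needs at least 3 labels")
  if (max(abs(d - t(d))) > 1e-9) stop("distance matrix is not symmetric")
  tr <- ape::nj(d)
  if (any(tr$edge.length < 0)) {
    warning("clamping ", sum(tr$edge.length < 0),
            " negative branch length(s) to 0")
    tr$edge.length[tr$edge.length < 0] <- 0
  }
  tr
}

# Greedily pick up to n windows at least min_spacing apart (gap between the
# end of one and the start of the next) from candidate windows taken in the
# given order. Returns row indices into `windows`.
pick_spaced_windows <- function(windows, n, min_spacing, order_idx) {
  chosen_start <- list()
  chosen_end <- list()
  out <- integer(0)
  for (i in order_idx) {
    ch <- windows$chrom[i]
    s <- windows$start[i]; e <- windows$end[i]
    ok <- TRUE
    if (!is.null(chosen_start[[ch]])) {
      gap_ok <- (s >= chosen_end[[ch]] + min_spacing) |
        (e + min_spacing <= chosen_start[[ch]])
      ok <- all(gap_ok)
    }
    if (ok) {
      chosen_start[[ch]] <- c(chosen_start[[ch]], s)
      chosen_end[[ch]] <- c(chosen_end[[ch]], e)
      out <- c(out, i)
      if (length(out) == n) break
    }
  }
  out
}

#' Window-resampling bootstrap support for the Fst NJ tree
#'
#' The full-data tree is built from the average windowed Fst over all
#' windows. Each bootstrap replicate randomly samples `n_windows` windows
#' (without replacement, at least `min_spacing` bp apart, greedily on a
#' shuffled candidate list), rebuilds the Fst matrix and NJ tree, and the
#' support of each internal bipartition of the full-data tree is the
#' percentage of replicate trees containing it.
#'
#' @param gm a [genotype_matrix()].
#' @param popmap a [population_map()].
#' @param n_windows windows per replicate (default 5000).
#' @param window_size window size in bp (default 10 kb).
#' @param min_spacing minimum gap between sampled windows (default 100 kb).
#' @param replicates number of bootstrap replicates (default 100).
#' @param seed integer seed.
#' @return list with `tree` (full-data tree, node labels = support %),
#'   `replicates` (`multiPhylo`), `support` (per internal node), `consensus`
#'   (majority-rule consensus of the replicates).
#' @export
bootstrap_support <- function(gm, popmap, n_windows = 5000,
                              window_size = 1e4, min_spacing = 1e5,
                              replicates = 100, seed = 1) {
  set.seed(seed)
  windows <- make_windows(infer_chrom_lengths(gm$sites, window_size),
                          window_size)
  feasible <- length(pick_spaced_windows(windows, nrow(windows), min_spacing,
                                         seq_len(nrow(windows))))
  if (feasible < n_windows) {
    stop("spacing constraint allows at most ", feasible,
         " windows; ", n_windows, " requested")
  }
  pops <- unique(popmap$population)
  ws <- fst_window_sums(gm, popmap, pops, windows)
  full <- neighbor_joining(dist_from_sums(ws))
  reps <- vector("list", replicates)
  for (r in seq_len(replicates)) {
    ord <- sample.int(nrow(windows))
    widx <- pick_spaced_windows(windows, n_windows, min_spacing, ord)
    reps[[r]] <- suppressWarnings(neighbor_joining(dist_from_sums(ws, widx)))
  }
  class(reps) <- "multiPhylo"
  counts <- ape::prop.clades(full, reps, rooted = FALSE)
  counts[is.na(counts)] <- 0
  support <- 100 * counts / replicates
  tree <- full
  tree$node.label <- round(support, 1)
  cons <- majority_consensus(reps)
  list(tree = tree, replicates = reps, support = support, consensus = cons)
}

#' Majority-rule consensus tree
#'
#' Bipartitions present in strictly more than half of the trees are
#' retained (greedy compatible completion via ape); node labels carry the
#' occurrence percentage of each retained bipartition.
#'
#' @param trees a list or `multiPhylo` of trees on identical leaf sets.
#' @return a `phylo` consensus tree with support node labels.
#' @export
majority_consensus <- function(trees) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  class(trees) <- "multiPhylo"
  labs <- lapply(trees, function(t) sort(t$tip.label))
  if (length(unique(vapply(labs, paste, character(1), collapse = ","))) > 1) {
    stop("trees have mismatching leaf sets")
  }
  cons <- ape::consensus(trees, p = 0.5, check.labels = TRUE)
  counts <- ape::prop.clades(cons, trees, rooted = FALSE)
  counts[is.na(counts)] <- length(trees)
  cons$node.label <- round(100 * counts / length(trees), 1)
  cons
}

#' Newick serialization
#'
#' Writes/reads trees in newick format with branch lengths and (when
#' present) support node labels; a write/read round trip preserves
#' topology, branch lengths to 1e-9 and supports exactly.
#'
#' @param tree a `phylo` tree.
#' @param path file path.
#' @return `read_newick` returns a `phylo`; `write_newick` returns `path`
#'   invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' @rdname write_newick
#' @export
read_newick <- function(path) {
  tr <- tryCatch(ape::read.tree(path),
                 error = function(e) stop("malformed newick in ", path, ": ",
                                          conditionMessage(e)))
  if (is.null(tr)) stop("malformed newick in ", path)
  tr
}

#' Robinson-Foulds distance between two trees
#'
#' Number of bipartitions present in one tree but not the other
#' (unrooted topological distance).
#'
#' @param t1,t2 `phylo` trees on the same leaf set.
#' @return integer distance.
#' @export
robinson_foulds <- function(t1, t2) {
  as.numeric(ape::dist.topo(ape::unroot(t1), ape::unroot(t2),
                            method = "PH85"))
}
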