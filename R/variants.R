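#' Read a multi-sample VCF into a genotype matrix
#'
#' Parsing is delegated to vcfR; genotypes are recoded as alternate-allele
#' dosages. Any genotype containing a missing allele (including half-calls
#' like `./1`) is coded `NA`. Multiallelic records are preserved with their
#' full allele list; their dosage counts any non-reference allele, and the
#' biallelic filter rule removes them downstream.
#'
#' @param path VCF file (plain or gzipped).
#' @return A [genotype_matrix()].
#' @export
read_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  dp <- suppressWarnings(as.numeric(vcfR::extract.info(v, "DP")))
  mq <- suppressWarnings(as.numeric(vcfR::extract.info(v, "MQ")))
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = nrow(fix))
  # dosage: count non-"0" alleles; any "." allele makes the call missing
  code_gt <- function(x) {
    al <- strsplit(x, "[/|]")
    vapply(al, function(a) {
      if (length(a) == 0 || anyNA(a) || any(a == ".")) return(NA_integer_)
      sum(a != "0")
    }, integer(1))
  }
  g <- apply(gt, 2, code_gt)
  if (is.null(dim(g))) g <- matrix(g, nrow = nrow(fix))
  g[is.na(gt)] <- NA_integer_
  sites <- data.frame(chrom = fix[, "CHROM"],
                      pos = as.numeric(fix[, "POS"]),
                      ref = fix[, "REF"],
                      alt = fix[, "ALT"],
                      qual = suppressWarnings(as.numeric(fix[, "QUAL"])),
                      dp = dp, mq = mq)
  genotype_matrix(sites, g, colnames(gt))
}

#' Write a genotype matrix as VCF v4.2
#'
#' Emits one record per site with QUAL, `INFO DP` (depth summed over
#' samples), `INFO MQ` (RMS mapping quality) and diploid GT calls
#' (`0/0`, `0/1`, `1/1`, missing `./.`). Round-trips losslessly through
#' [read_vcf()].
#'
#' @param gm a [genotype_matrix()].
#' @param path output path.
#' @export
write_vcf <- function(gm, path) {
  sites <- gm$sites
  chroms <- unique(sites$chrom)
  contig <- vapply(chroms, function(ch)
    sprintf("##contig=<ID=%s,length=%d>", ch,
            as.integer(max(sites$pos[sites$chrom == ch]))), character(1))
  hdr <- c("##fileformat=VCFv4.2",
           "##source=camelscan",
           contig,
           "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Total depth summed over samples\">",
           "##INFO=<ID=MQ,Number=1,Type=Float,Description=\"RMS mapping quality\">",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", gm$samples), collapse = "\t"))
  gt_str <- c("0/0", "0/1", "1/1")
  gchr <- matrix("./.", nrow(gm$geno), ncol(gm$geno))
  ok <- !is.na(gm$geno)
  gchr[ok] <- gt_str[gm$geno[ok] + 1L]
  body <- if (nrow(sites)) {
    info <- sprintf("DP=%d;MQ=%s", as.integer(sites$dp),
                    format(sites$mq, trim = TRUE, scientific = FALSE))
    fixed <- data.frame(sites$chrom, as.integer(sites$pos), ".", sites$ref,
                        sites$alt, format(sites$qual, trim = TRUE,
                                          scientific = FALSE),
                        "PASS", info, "GT")
    do.call(paste, c(unname(fixed),
                     lapply(seq_len(ncol(gchr)), function(j) gchr[, j]),
                     sep = "\t"))
  } else character(0)
  con <- file(path, "w")
  on.exit(close(con))
  ok <- tryCatch({
    writeLines(c(hdr, body), con)
    TRUE
  }, error = function(e) {
    stop("failed writing VCF to ", path, ": ", conditionMessage(e))
  })
  invisible(path)
}

#' Apply the panel's variant filters
#'
#' A record survives when it passes every active rule: variant quality
#' `QUAL > qual_min`, summed depth `dp_min < DP < dp_max`, minor allele
#' frequency `MAF > maf_min` (computed from non-missing alleles over all
#' samples), fraction of individuals with a missing genotype `< miss_max`,
#' RMS mapping quality `MQ > mq_min`, and exactly one alternate allele.
#' Inequalities are strict. Set a threshold to `NULL` to disable that rule.
#' Defaults reproduce the published criteria.
#'
#' @param gm a [genotype_matrix()].
#' @param qual_min,dp_min,dp_max,maf_min,miss_max,mq_min,biallelic rule
#'   thresholds (see description); `biallelic` is logical.
#' @return list with `genotypes` (filtered matrix) and `report`
#'   (a `filter_report`: input/output counts and per-rule removal tallies; a
#'   record failing several rules is counted in each tally).
#' @export
filter_variants <- function(gm, qual_min = 40, dp_min = 200, dp_max = 5000,
                            maf_min = 0.01, miss_max = 0.20, mq_min = 30,
                            biallelic = TRUE) {
  s <- gm$sites
  n <- nrow(s)
  m <- ncol(gm$geno)
  fails <- list()
  need <- function(field, rule) {
    v <- s[[field]]
    if (is.null(v) || (length(v) && all(is.na(v)))) {
      stop("filter rule '", rule, "' needs site metadata field '", field, "'")
    }
    v
  }
  if (!is.null(qual_min)) {
    fails$qual <- !(need("qual", "qual") > qual_min)
  }
  if (!is.null(dp_min) || !is.null(dp_max)) {
    dp <- need("dp", "depth")
    lo <- if (is.null(dp_min)) -Inf else dp_min
    hi <- if (is.null(dp_max)) Inf else dp_max
    fails$depth <- !(dp > lo & dp < hi)
  }
  if (!is.null(maf_min)) {
    ac <- rowSums(gm$geno, na.rm = TRUE)
    an <- 2L * rowSums(!is.na(gm$geno))
    p <- ifelse(an > 0, ac / an, NA_real_)
    maf <- pmin(p, 1 - p)
    fails$maf <- !(!is.na(maf) & maf > maf_min)
  }
  if (!is.null(miss_max)) {
    fr <- rowSums(is.na(gm$geno)) / m
    fails$missing <- !(fr < miss_max)
  }
  if (!is.null(mq_min)) {
    fails$mq <- !(need("mq", "mq") > mq_min)
  }
  if (isTRUE(biallelic)) {
    n_alt <- lengths(strsplit(as.character(s$alt), ",", fixed = TRUE))
    fails$biallelic <- !(n_alt == 1 & s$alt != ".")
  }
  if (length(fails)) {
    fail_any <- Reduce(`|`, fails)
  } else {
    fail_any <- rep(FALSE, n)
  }
  keep <- !fail_any
  report <- structure(list(input_count = n,
                           output_count = sum(keep),
                           removed = vapply(fails, sum, integer(1))),
                      class = "filter_report")
  list(genotypes = subset_sites(gm, keep), report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat("filter_report:", x$input_count, "->", x$output_count, "records\n")
  for (nm in names(x$removed)) {
    cat(sprintf("  %-10s removed %d\n", nm, x$removed[[nm]]))
  }
  invisible(x)
}

#' Transition:transversion ratio
#'
#' Transitions are A<->G and C<->T; everything else among single-base
#' ref/alt pairs is a transversion. Indels and multiallelic records are
#' skipped (and counted in the attributes). Returns `NA` with a warning when
#' no transversion is observed.
#'
#' @param gm a [genotype_matrix()].
#' @return the ratio (numeric), with attributes `ts`, `tv`, `skipped`.
#' @export
ts_tv_ratio <- function(gm) {
  ref <- toupper(gm$sites$ref)
  alt <- toupper(gm$sites$alt)
  snp <- ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  pair <- paste0(ref[snp], alt[snp])
  ts <- sum(pair %in% c("AG", "GA", "CT", "TC"))
  tv <- sum(snp) - ts
  out <- if (tv == 0) {
    warning("no transversions observed; Ts/Tv undefined")
    NA_real_
  } else ts / tv
  attr(out, "ts") <- ts
  attr(out, "tv") <- tv
  attr(out, "skipped") <- sum(!snp)
  out
}

#' Shared and private variant counts between groups
#'
#' A variant is "identified in" a group when at least one non-missing
#' alternate allele is called among the group's samples. Reports per-group
#' totals, pairwise intersection counts, shared fractions
#' `|A n B| / |A|` (rows = A), and private counts (variants seen in exactly
#' one group).
#'
#' @param gm a [genotype_matrix()].
#' @param popmap a [population_map()].
#' @param groups named list mapping group name -> population/group labels;
#'   defaults to the popmap's `group` column.
#' @return list with `totals`, `shared_counts`, `shared_fraction`, `private`.
#' @export
shared_private_counts <- function(gm, popmap, groups = NULL) {
  if (is.null(groups)) {
    groups <- split(unique(popmap$group), unique(popmap$group))
  }
  present <- sapply(names(groups), function(gname) {
    ids <- samples_for(popmap, groups[[gname]])
    sub <- gm$geno[, gm$samples %in% ids, drop = FALSE]
    rowSums(sub > 0, na.rm = TRUE) > 0
  })
  if (is.null(dim(present))) present <- matrix(present, nrow = 1,
                                               dimnames = list(NULL, names(groups)))
  totals <- colSums(present)
  k <- ncol(present)
  shared <- crossprod(present)  # |A n B|
  frac <- sweep(shared, 1, pmax(totals, 1), "/")
  frac[totals == 0, ] <- NA_real_
  private <- colSums(present & rowSums(present) == 1)
  list(totals = totals, shared_counts = shared,
       shared_fraction = frac, private = private)
}

#' Greedy LD pruning of variants
#'
#' PLINK-style `--indep-pairwise` scan: within each window of `window_size`
#' variants (advancing by `step`), while any pair of still-kept variants has
#' squared dosage correlation above `r2_threshold`, the later variant of the
#' worst offending pair is dropped. Missing genotypes are excluded pairwise.
#' Deterministic.
#'
#' @param gm a [genotype_matrix()].
#' @param window_size,step window size and step, in variants (defaults 50/5).
#' @param r2_threshold r-squared above which a pair is pruned (default 0.5).
#' @return integer vector of kept site indices.
#' @export
ld_prune <- function(gm, window_size = 50, step = 5, r2_threshold = 0.5) {
  n <- nrow(gm$geno)
  keep <- rep(TRUE, n)
  if (n < 2) return(which(keep))
  starts <- seq(1, n, by = step)
  for (s in starts) {
    e <- min(s + window_size - 1, n)
    if (e <= s) next
    idx <- s:e
    repeat {
      live <- idx[keep[idx]]
      if (length(live) < 2) break
      G <- gm$geno[live, , drop = FALSE]
      r2 <- suppressWarnings(
        stats::cor(t(G), use = "pairwise.complete.obs"))^2
      r2[!is.finite(r2)] <- 0
      diag(r2) <- 0
      mx <- max(r2)
      if (mx <= r2_threshold) break
      w <- which(r2 == mx, arr.ind = TRUE)[1, ]
      keep[max(live[w])] <- FALSE
    }
    if (e == n) break
  }
  which(keep)
}

# Merge 0-based half-open intervals per chromosome.
merge_intervals <- function(iv) {
  if (!nrow(iv)) return(iv)
  out <- lapply(split(iv, iv$chrom), function(d) {
    d <- d[order(d$start), , drop = FALSE]
    st <- d$start[1]; en <- d$end[1]
    res <- list()
    for (i in seq_len(nrow(d))[-1]) {
      if (d$start[i] <= en) en <- max(en, d$end[i]) else {
        res[[length(res) + 1]] <- c(st, en); st <- d$start[i]; en <- d$end[i]
      }
    }
    res[[length(res) + 1]] <- c(st, en)
    m <- do.call(rbind, res)
    data.frame(chrom = d$chrom[1], start = m[, 1], end = m[, 2])
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Select putatively neutral loci outside excluded regions
#'
#' Places fixed-length loci wholly outside the exclusion intervals with at
#' least `min_gap` bp between the end of one locus and the start of the
#' next, stopping at `max_count` or exhaustion. Two placement modes:
#' `"random"` draws candidate starts uniformly in the free space, sorts
#' them, and accepts greedily (deterministic given `seed`); `"packed"`
#' places loci earliest-first and realizes the maximum packing.
#'
#' @param chromosome_lengths named numeric vector (bp).
#' @param exclusion_intervals data.frame `chrom`, `start`, `end`
#'   (0-based half-open); merged internally.
#' @param locus_length locus size in bp (default 1000).
#' @param min_gap minimum gap between consecutive loci (default 30000).
#' @param max_count maximum number of loci (default 10000).
#' @param seed integer seed for random placement.
#' @param method `"random"` or `"packed"`.
#' @return data.frame `chrom`, `start`, `end` (0-based half-open), sorted.
#' @export
select_neutral_loci <- function(chromosome_lengths, exclusion_intervals,
                                locus_length = 1000, min_gap = 30000,
                                max_count = 10000, seed = 1,
                                method = c("random", "packed")) {
  method <- match.arg(method)
  set.seed(seed)
  free <- list()
  for (ch in names(chromosome_lengths)) {
    len <- chromosome_lengths[[ch]]
    ex <- exclusion_intervals[exclusion_intervals$chrom == ch, , drop = FALSE]
    ex <- merge_intervals(ex)
    st <- 0
    for (i in seq_len(nrow(ex))) {
      if (ex$start[i] > st) {
        free[[length(free) + 1]] <- data.frame(chrom = ch, start = st,
                                               end = ex$start[i])
      }
      st <- max(st, ex$end[i])
    }
    if (st < len) {
      free[[length(free) + 1]] <- data.frame(chrom = ch, start = st,
                                             end = len)
    }
  }
  free <- do.call(rbind, free)
  free <- free[free$end - free$start >= locus_length, , drop = FALSE]
  if (is.null(free) || !nrow(free)) {
    warning("no free interval can hold a locus of ", locus_length, " bp")
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric()))
  }
  loci <- list()
  for (ch in unique(free$chrom)) {
    fr <- free[free$chrom == ch, , drop = FALSE]
    if (method == "packed") {
      starts <- numeric(0)
      for (i in seq_len(nrow(fr))) {
        s <- fr$start[i]
        if (length(starts)) {
          s <- max(s, starts[length(starts)] + locus_length + min_gap)
        }
        while (s + locus_length <= fr$end[i]) {
          starts <- c(starts, s)
          s <- s + locus_length + min_gap
        }
      }
    } else {
      # candidate starts uniform in free space, sorted, greedy acceptance
      span <- fr$end - fr$start - locus_length
      ncand <- min(10L * max_count + 100L, 200000L)
      wi <- sample.int(nrow(fr), ncand, replace = TRUE,
                       prob = span + 1)
      cand <- sort(fr$start[wi] + floor(stats::runif(ncand) * (span[wi] + 1)))
      ivl <- findInterval(cand, fr$start)
      ok <- cand + locus_length <= fr$end[ivl]
      cand <- cand[ok]
      starts <- numeric(0)
      last_end <- -Inf
      for (s in cand) {
        if (s >= last_end + min_gap) {
          starts <- c(starts, s)
          last_end <- s + locus_length
        }
      }
    }
    if (length(starts)) {
      loci[[length(loci) + 1]] <- data.frame(chrom = ch, start = starts,
                                             end = starts + locus_length)
    }
  }
  out <- if (length(loci)) do.call(rbind, loci) else
    data.frame(chrom = character(), start = numeric(), end = numeric())
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  utils::head(out, max_count)
}
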