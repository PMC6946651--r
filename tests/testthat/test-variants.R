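test_that("the published filter rules leave exactly one survivor on the toy panel", {
  gm <- toy_filter_gm()
  # rule enumeration oracle, record by record:
  # r1 passes all; r2 fails QUAL (30 <= 40); r3 fails biallelic;
  # r4 fails MAF (0.005 <= 0.01)
  res <- filter_variants(gm)
  expect_identical(res$report$input_count, 4L)
  expect_identical(res$report$output_count, 1L)
  expect_identical(res$genotypes$sites$pos, 100)
  expect_identical(unname(res$report$removed[c("qual", "maf", "biallelic")]),
                   c(1L, 1L, 1L))
  expect_identical(unname(res$report$removed[c("depth", "missing", "mq")]),
                   c(0L, 0L, 0L))
})

test_that("filtering is idempotent and disabled rules give the identity", {
  gm <- random_gm(200, 12, seed = 5)
  once <- filter_variants(gm)
  twice <- filter_variants(once$genotypes)
  expect_identical(twice$genotypes$sites, once$genotypes$sites)
  expect_identical(twice$genotypes$geno, once$genotypes$geno)

  off <- filter_variants(gm, qual_min = NULL, dp_min = NULL, dp_max = NULL,
                         maf_min = NULL, miss_max = NULL, mq_min = NULL,
                         biallelic = FALSE)
  expect_identical(off$genotypes$geno, gm$geno)
  expect_identical(off$report$output_count, off$report$input_count)

  empty <- filter_variants(gm, qual_min = 1e9)
  expect_identical(empty$report$output_count, 0L)
  refilter <- filter_variants(empty$genotypes)
  expect_identical(refilter$report$input_count, 0L)
  expect_identical(refilter$report$output_count, 0L)
})

test_that("survivors are invariant to the order rules are applied in", {
  gm <- random_gm(300, 10, seed = 6)
  all_at_once <- filter_variants(gm, dp_min = 380, dp_max = 420,
                                 qual_min = 50, mq_min = 35)
  staged <- filter_variants(gm, qual_min = NULL, dp_min = 380, dp_max = 420,
                            maf_min = NULL, miss_max = NULL, mq_min = NULL,
                            biallelic = FALSE)
  staged <- filter_variants(staged$genotypes, qual_min = 50, dp_min = NULL,
                            dp_max = NULL, mq_min = 35)
  expect_identical(staged$genotypes$sites, all_at_once$genotypes$sites)
})

test_that("Ts/Tv counts transitions against transversions", {
  gm <- gm_from_geno(matrix(1, 3, 4))
  gm$sites$ref <- c("A", "C", "A")
  gm$sites$alt <- c("G", "T", "C")
  expect_equal(as.numeric(ts_tv_ratio(gm)), 2.0)

  gm$sites$alt <- c("G", "T", "T")  # third site A->T, still a transversion
  expect_equal(as.numeric(ts_tv_ratio(gm)), 2.0)

  gm2 <- gm_from_geno(matrix(1, 2, 4))
  gm2$sites$ref <- c("A", "C"); gm2$sites$alt <- c("G", "T")
  expect_warning(r <- ts_tv_ratio(gm2), "undefined")
  expect_true(is.na(r))
})

test_that("sampled allele pairs reproduce the target Ts/Tv within binomial bounds", {
  tr <- data.frame(child = c("A", "B"), parent = "root", F = 0.1)
  cfg <- scenario_config(tr, n_sites = 1000, target_ts_tv = 2.4,
                         chromosome_lengths = c(chr1 = 2e5),
                         samples_per_population = 3, seed = 31)
  sim <- simulate_scenario(cfg)
  r <- as.numeric(ts_tv_ratio(sim$genotypes))
  k <- qbinom(c(0.005, 0.995), 1000, 2.4 / 3.4)
  expect_gte(r, k[1] / (1000 - k[1]))
  expect_lte(r, k[2] / (1000 - k[2]))
})

test_that("shared and private variant counts match enumeration", {
  # group A (2 samples) alt at sites 1,2; group B alt at sites 2,3
  g <- rbind(c(1, 0, 0, 0),
             c(0, 1, 1, 0),
             c(0, 0, 0, 2))
  gm <- gm_from_geno(g)
  pm <- population_map(gm$samples, c("A", "A", "B", "B"))
  sp <- shared_private_counts(gm, pm, groups = list(A = "A", B = "B"))
  expect_equal(unname(sp$totals), c(2, 2))
  expect_equal(sp$shared_counts["A", "B"], 1)
  expect_equal(sp$shared_fraction["A", "B"], 0.5)
  expect_equal(unname(sp$private), c(1, 1))
  expect_equal(sp$shared_fraction["A", "A"], 1)

  # a group with all genotypes missing identifies nothing
  g2 <- cbind(c(1, 1), c(NA, NA))
  gm2 <- gm_from_geno(g2)
  pm2 <- population_map(gm2$samples, c("A", "B"))
  sp2 <- shared_private_counts(gm2, pm2, groups = list(A = "A", B = "B"))
  expect_equal(unname(sp2$totals), c(2, 0))
})

test_that("LD pruning keeps the earlier duplicate and leaves independent variants", {
  set.seed(2)
  base <- rbinom(30, 2, 0.5)
  g <- rbind(base, base, matrix(rbinom(5 * 30, 2, 0.5), 5))
  gm <- gm_from_geno(g)
  kept <- ld_prune(gm)
  expect_true(1 %in% kept)
  expect_false(2 %in% kept)

  set.seed(3)
  indep <- matrix(rbinom(10 * 400, 2, 0.5), 10)
  gmi <- gm_from_geno(indep)
  expect_identical(ld_prune(gmi), 1:10)
})

test_that("pruned sets satisfy the r2 bound and are greedily maximal", {
  set.seed(11)
  n <- 10
  base <- matrix(rbinom(3 * 60, 2, 0.5), 3)
  g <- base[sample(1:3, n, replace = TRUE), ]
  g <- g + matrix(rbinom(n * 60, 1, 0.15), n)
  g[g > 2] <- 2
  gm <- gm_from_geno(g)
  kept <- ld_prune(gm, window_size = 10, step = 5, r2_threshold = 0.5)
  r2 <- suppressWarnings(cor(t(g[kept, , drop = FALSE]),
                             use = "pairwise.complete.obs"))^2
  diag(r2) <- 0
  expect_true(all(r2 <= 0.5 + 1e-12))
  # greedy maximality: pruning the pruned set removes nothing further
  expect_identical(ld_prune(gm_from_geno(g[kept, ]), window_size = 10,
                            step = 5, r2_threshold = 0.5),
                   seq_along(kept))
})

test_that("neutral-locus packing matches the arithmetic bound", {
  excl <- data.frame(chrom = "chr1", start = 0, end = 2e5)
  loci <- select_neutral_loci(c(chr1 = 1e6), excl, method = "packed")
  # free space [200 kb, 1 Mb): loci every 31 kb starting at 200,000
  expect_identical(nrow(loci), 26L)
  expect_equal(loci$start[1], 2e5)
  expect_true(all(diff(loci$start) >= 31000))

  covered <- data.frame(chrom = "chr1", start = 0, end = 1e6)
  expect_warning(none <- select_neutral_loci(c(chr1 = 1e6), covered),
                 "free interval")
  expect_identical(nrow(none), 0L)

  one <- select_neutral_loci(c(chr1 = 5e4),
                             data.frame(chrom = character(),
                                        start = numeric(), end = numeric()),
                             locus_length = 5e4, min_gap = 0)
  expect_identical(nrow(one), 1L)
})

test_that("random locus placement respects exclusions, gaps and determinism", {
  excl <- data.frame(chrom = "chr1", start = c(1e5, 4e5), end = c(2e5, 5e5))
  a <- select_neutral_loci(c(chr1 = 1e6), excl, max_count = 15, seed = 7)
  b <- select_neutral_loci(c(chr1 = 1e6), excl, max_count = 15, seed = 7)
  expect_identical(a, b)
  expect_lte(nrow(a), 15)
  expect_true(all(a$end - a$start == 1000))
  expect_true(all(diff(a$start) - 1000 >= 30000))
  overlaps_excl <- any(a$start < excl$end[1] & a$end > excl$start[1]) ||
    any(a$start < excl$end[2] & a$end > excl$start[2])
  expect_false(overlaps_excl)
})

test_that("the VCF reader flags unsorted input and codes half-calls missing", {
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"d\">",
    "##INFO=<ID=MQ,Number=1,Type=Float,Description=\"m\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"g\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1\ts2",
    "chr1\t100\t.\tA\tG\t50\tPASS\tDP=300;MQ=40\tGT\t0/1\t./.",
    "chr1\t200\t.\tC\tT\t50\tPASS\tDP=300;MQ=40\tGT\t./1\t1|1"),
    path)
  gm <- read_vcf(path)
  expect_identical(gm$geno[1, ], c(s1 = 1L, s2 = NA_integer_))
  expect_identical(gm$geno[2, ], c(s1 = NA_integer_, s2 = 2L))

  bad <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"g\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1",
    "chr1\t200\t.\tA\tG\t50\tPASS\t.\tGT\t0/1",
    "chr1\t100\t.\tC\tT\t50\tPASS\t.\tGT\t0/0"),
    bad)
  expect_error(read_vcf(bad), "increasing")
})

test_that("total migration rate is the product of rate and time span", {
  expect_identical(total_migration_rate(0, 5), 0)
  expect_equal(total_migration_rate(0.001, 2.7), 0.0027)
  set.seed(1)
  m <- runif(20); tau <- runif(20)
  expect_equal(total_migration_rate(m, tau), m * tau)
  expect_error(total_migration_rate(-1, 1), "nonnegative")
})
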