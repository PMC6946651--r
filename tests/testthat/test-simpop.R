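sister_tree <- function(F = 0.1) {
  data.frame(child = c("A", "B"), parent = "root", F = F)
}

test_that("zero drift and full replacement are exact identities", {
  cfg <- scenario_config(sister_tree(0), n_sites = 200,
                         chromosome_lengths = c(chr1 = 1e5), seed = 4)
  sim <- simulate_frequencies(cfg)
  expect_identical(sim$freqs$p[, "A"], sim$freqs$p[, "B"])

  wins <- data.frame(chrom = "chr1", start = 0, end = 1e5)
  cfg2 <- scenario_config(sister_tree(0.2),
                          admixture_pulses = list(
                            list(donor = "A", recipient = "B", f = 1,
                                 windows = wins)),
                          n_sites = 200, chromosome_lengths = c(chr1 = 1e5),
                          seed = 4)
  sim2 <- simulate_frequencies(cfg2)
  expect_equal(sim2$freqs$p[, "B"], sim2$freqs$p[, "A"])
})

test_that("sister populations at F = 0.1 realize Weir-Cockerham Fst near 0.1", {
  cfg <- scenario_config(sister_tree(0.1), n_sites = 50000, site_spacing = 20,
                         chromosome_lengths = c(chr1 = 1.1e6),
                         missing_rate = 0, samples_per_population = 20,
                         seed = 42)
  sim <- simulate_scenario(cfg)
  fst <- weir_fst(sim$genotypes, sim$popmap, "A", "B")$overall
  expect_lt(abs(fst - 0.1), 0.02)
})

test_that("expected Fst to the sister increases monotonically with branch F", {
  vals <- vapply(c(0.05, 0.15, 0.3), function(Fb) {
    tr <- data.frame(child = c("A", "B"), parent = "root", F = c(0.05, Fb))
    cfg <- scenario_config(tr, n_sites = 30000, site_spacing = 20,
                           chromosome_lengths = c(chr1 = 6.1e5),
                           missing_rate = 0, samples_per_population = 15,
                           seed = 99)
    sim <- simulate_scenario(cfg)
    weir_fst(sim$genotypes, sim$popmap, "A", "B")$overall
  }, numeric(1))
  expect_true(all(diff(vals) > 0))
})

test_that("genotype sampling respects degenerate frequencies and Hardy-Weinberg", {
  cfg <- scenario_config(sister_tree(0), n_sites = 3,
                         chromosome_lengths = c(chr1 = 1e4),
                         missing_rate = 0, samples_per_population = 1000,
                         seed = 8)
  fr <- structure(list(sites = data.frame(chrom = "chr1",
                                          pos = c(100, 200, 300)),
                       p = cbind(A = c(0, 1, 0.5), B = c(0, 1, 0.5)),
                       populations = c("A", "B")),
                  class = "freq_table")
  gs <- sample_genotypes(fr, cfg)
  g <- gs$genotypes$geno
  expect_true(all(g[1, ] == 0))
  expect_true(all(g[2, ] == 2))
  counts <- table(factor(g[3, gs$popmap$population == "A"], levels = 0:2))
  # Binomial(2, 0.5) over 1000 diploids: 250/500/250 within 3 sigma
  expect_lt(abs(counts[[1]] - 250), 3 * sqrt(1000 * 0.25 * 0.75))
  expect_lt(abs(counts[[2]] - 500), 3 * sqrt(1000 * 0.5 * 0.5))
  expect_lt(abs(counts[[3]] - 250), 3 * sqrt(1000 * 0.25 * 0.75))

  cfg_miss <- scenario_config(sister_tree(0), n_sites = 50,
                              chromosome_lengths = c(chr1 = 1e4),
                              missing_rate = 1, samples_per_population = 5,
                              seed = 8)
  sim <- simulate_scenario(cfg_miss)
  expect_true(all(is.na(sim$genotypes$geno)))
})

test_that("invalid configurations are rejected", {
  expect_error(scenario_config(sister_tree(1.0)), "\\[0, 1\\)")
  expect_error(scenario_config(data.frame(child = character(),
                                          parent = character(),
                                          F = numeric())), "empty")
  expect_error(scenario_config(sister_tree(0.1), missing_rate = 1.5),
               "missing_rate")
  expect_error(scenario_config(
    sister_tree(0.1),
    admixture_pulses = list(list(donor = "A", recipient = "B", f = 0.5,
                                 windows = data.frame(chrom = "chr1",
                                                      start = 0,
                                                      end = 2e6)))),
    "outside")
})

test_that("camel scenario has dromedary pulses into exactly the Central Asians", {
  cfg <- make_camel_scenario(n_sites = 1000)
  rec <- sort(unique(vapply(cfg$admixture_pulses, `[[`, character(1),
                            "recipient")))
  don <- unique(vapply(cfg$admixture_pulses, `[[`, character(1), "donor"))
  expect_identical(rec, c("IRAN", "KAZA", "RUS"))
  expect_identical(don, "drom")
  fs <- vapply(cfg$admixture_pulses, `[[`, numeric(1), "f")
  expect_true(all(fs >= 0.01 & fs <= 0.10))

  cfg0 <- make_camel_scenario(n_sites = 1000, pulse_f = numeric(0))
  sim0 <- simulate_frequencies(cfg0)
  expect_identical(nrow(sim0$truth$introgressed_windows), 0L)
})

test_that("pulses are local: frequencies outside affected windows are untouched", {
  wins <- data.frame(chrom = "chr1", start = 0, end = 5e4)
  base <- scenario_config(sister_tree(0.2), n_sites = 1000,
                          chromosome_lengths = c(chr1 = 2e5), seed = 17)
  pulsed <- scenario_config(sister_tree(0.2),
                            admixture_pulses = list(
                              list(donor = "A", recipient = "B", f = 0.5,
                                   windows = wins)),
                            n_sites = 1000,
                            chromosome_lengths = c(chr1 = 2e5), seed = 17)
  f0 <- simulate_frequencies(base)$freqs
  f1 <- simulate_frequencies(pulsed)$freqs
  outside <- f0$sites$pos > 5e4
  expect_identical(f1$p[outside, "B"], f0$p[outside, "B"])
  expect_false(isTRUE(all.equal(f1$p[!outside, "B"], f0$p[!outside, "B"])))
})

test_that("outputs are deterministic and round-trip through the VCF reader", {
  cfg <- scenario_config(sister_tree(0.15), n_sites = 300,
                         chromosome_lengths = c(chr1 = 1e5),
                         missing_rate = 0.1, samples_per_population = 4,
                         seed = 23)
  sim <- simulate_scenario(cfg)
  d1 <- withr::local_tempdir()
  p1 <- write_outputs(sim$genotypes, sim$popmap, sim$truth,
                      file.path(d1, "a"))
  p2 <- write_outputs(sim$genotypes, sim$popmap, sim$truth,
                      file.path(d1, "b"))
  expect_identical(unname(tools::md5sum(p1)), unname(tools::md5sum(p2)))

  gm2 <- read_vcf(p1[["vcf"]])
  expect_identical(gm2$geno, sim$genotypes$geno)
  expect_equal(gm2$sites$pos, sim$genotypes$sites$pos)
  expect_equal(gm2$sites$qual, sim$genotypes$sites$qual)
  expect_identical(gm2$sites$ref, sim$genotypes$sites$ref)
  pm2 <- read_popmap(p1[["popmap"]])
  expect_identical(pm2$population, sim$popmap$population)

  # rerunning the whole simulation reproduces byte-identical files
  sim_b <- simulate_scenario(cfg)
  d2 <- withr::local_tempdir()
  p3 <- write_outputs(sim_b$genotypes, sim_b$popmap, sim_b$truth,
                      file.path(d2, "a"))
  expect_identical(unname(tools::md5sum(p1)), unname(tools::md5sum(p3)))
})

test_that("truth BED lists every pulse window in coordinate order", {
  wins <- data.frame(chrom = "chr1", start = c(5e4, 0, 1e5),
                     end = c(6e4, 1e4, 1.1e5))
  cfg <- scenario_config(sister_tree(0.1),
                         admixture_pulses = list(
                           list(donor = "A", recipient = "B", f = 0.2,
                                windows = wins)),
                         n_sites = 100,
                         chromosome_lengths = c(chr1 = 2e5), seed = 3)
  sim <- simulate_frequencies(cfg)
  path <- withr::local_tempfile(fileext = ".bed")
  write_bed(sim$truth$introgressed_windows, path)
  bed <- read.table(path, sep = "\t")
  expect_identical(nrow(bed), 3L)
  expect_true(!is.unsorted(bed$V2))
})

test_that("empty genotype matrices still produce a valid header-only VCF", {
  gm <- genotype_matrix(data.frame(chrom = character(), pos = numeric(),
                                   ref = character(), alt = character(),
                                   qual = numeric(), dp = numeric(),
                                   mq = numeric()),
                        matrix(integer(), 0, 2), c("s1", "s2"))
  path <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(gm, path)
  lines <- readLines(path)
  expect_true(any(startsWith(lines, "##fileformat=VCFv4.2")))
  expect_identical(sum(!startsWith(lines, "#")), 0L)
})
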