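#' Pipeline configuration
#'
#' Declares the input (a simulation scenario or a VCF + population map on
#' disk), which stages to run, and the per-stage parameters. Stage
#' dependencies are validated before anything runs: `mask` needs `scan`,
#' `restat` needs `mask`, and `scan` needs a quartet.
#'
#' @param scenario a [scenario_config()], or NULL to read from files.
#' @param vcf,popmap input paths (used when `scenario` is NULL).
#' @param out_dir output directory (created if needed).
#' @param stages character vector among `simulate`, `filter`, `stats`,
#'   `scan`, `mask`, `restat`, `tree`.
#' @param quartet a [quartet_config()] for the scan stage.
#' @param filter_params named list of [filter_variants()] arguments.
#' @param window_size,block_size,z_threshold scan parameters.
#' @param stat_window_size window size for pi/theta/Fst (default 10 kb).
#' @param tree_params named list of [bootstrap_support()] arguments
#'   (`n_windows`, `min_spacing`, `replicates`).
#' @param seed master seed; per-stage seeds are fanned out from it by stable
#'   stage offsets.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(scenario = NULL, vcf = NULL, popmap = NULL,
                            out_dir = tempfile("camelscan_run_"),
                            stages = c("simulate", "filter", "stats", "scan",
                                       "mask", "restat", "tree"),
                            quartet = NULL,
                            filter_params = list(),
                            window_size = 1e5, block_size = 1e4,
                            z_threshold = 2,
                            stat_window_size = 1e4,
                            tree_params = list(n_windows = 100,
                                               min_spacing = 0,
                                               replicates = 100),
                            seed = 1) {
  known <- c("simulate", "filter", "stats", "scan", "mask", "restat", "tree")
  bad <- setdiff(stages, known)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  if (is.null(scenario) && (is.null(vcf) || is.null(popmap))) {
    stop("either a scenario or vcf + popmap paths must be given")
  }
  if ("simulate" %in% stages && is.null(scenario)) {
    stop("stage 'simulate' requires a scenario")
  }
  if ("mask" %in% stages && !("scan" %in% stages)) {
    stop("stage 'mask' requires stage 'scan'")
  }
  if ("restat" %in% stages && !("mask" %in% stages)) {
    stop("stage 'restat' requires stage 'mask'")
  }
  if ("scan" %in% stages && is.null(quartet)) {
    stop("stage 'scan' requires a quartet configuration")
  }
  if (window_size < block_size) stop("window_size must be >= block_size")
  structure(list(scenario = scenario, vcf = vcf, popmap = popmap,
                 out_dir = out_dir, stages = stages, quartet = quartet,
                 filter_params = filter_params, window_size = window_size,
                 block_size = block_size, z_threshold = z_threshold,
                 stat_window_size = stat_window_size,
                 tree_params = tree_params, seed = as.integer(seed)),
            class = "pipeline_config")
}

stage_seed <- function(config, stage) {
  offsets <- c(simulate = 0L, filter = 1L, stats = 2L, scan = 3L,
               mask = 4L, restat = 5L, tree = 6L)
  config$seed + offsets[[stage]]
}

#' Run the analysis pipeline
#'
#' Executes the enabled stages in dependency order: simulate (or ingest) ->
#' filter -> stats -> scan -> mask -> restat -> tree. Every intermediate
#' artifact is written in a standard text format (VCF, TSV, BED, newick)
#' under `out_dir`, and a JSON manifest records the seed, per-stage outputs,
#' their md5 checksums and wall-clock times.
#'
#' @param config a [pipeline_config()].
#' @return list with `manifest` (also written to `manifest.json`), and the
#'   in-memory stage results (`genotypes`, `popmap`, `stats`, `scan`,
#'   `masked`, `fst_before`, `fst_after`, `tree`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(seed = config$seed, stages = list())
  res <- list()
  t_stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    list(value = out, elapsed = proc.time()[["elapsed"]] - t0)
  }
  record <- function(name, files, elapsed) {
    files <- files[file.exists(files)]
    manifest$stages[[name]] <<- list(
      files = as.list(files),
      md5 = as.list(unname(tools::md5sum(files))),
      elapsed_s = round(elapsed, 3))
  }
  out_path <- function(...) file.path(config$out_dir, paste0(...))

  if ("simulate" %in% config$stages) {
    st <- t_stage("simulate", {
      sc <- config$scenario
      sc$seed <- stage_seed(config, "simulate")
      sim <- simulate_scenario(sc)
      paths <- write_outputs(sim$genotypes, sim$popmap, sim$truth,
                             out_path("sim"))
      list(sim = sim, paths = paths)
    })
    res$genotypes <- st$value$sim$genotypes
    res$popmap <- st$value$sim$popmap
    res$truth <- st$value$sim$truth
    record("simulate", st$value$paths, st$elapsed)
  } else {
    st <- t_stage("ingest", {
      list(gm = read_vcf(config$vcf), pm = read_popmap(config$popmap))
    })
    res$genotypes <- st$value$gm
    res$popmap <- st$value$pm
    record("ingest", c(config$vcf, config$popmap), st$elapsed)
  }

  if ("filter" %in% config$stages) {
    st <- t_stage("filter", {
      do.call(filter_variants, c(list(res$genotypes), config$filter_params))
    })
    res$genotypes <- st$value$genotypes
    res$filter_report <- st$value$report
    p <- out_path("filtered.vcf")
    write_vcf(res$genotypes, p)
    rp <- out_path("filter_report.json")
    jsonlite::write_json(list(input_count = st$value$report$input_count,
                              output_count = st$value$report$output_count,
                              removed = as.list(st$value$report$removed)),
                         rp, auto_unbox = TRUE)
    record("filter", c(p, rp), st$elapsed)
  }

  stat_windows <- make_windows(
    infer_chrom_lengths(res$genotypes$sites, config$stat_window_size),
    config$stat_window_size)

  if ("stats" %in% config$stages) {
    st <- t_stage("stats", {
      pops <- unique(res$popmap$population)
      pi_tabs <- lapply(pops, function(p)
        cbind(pop = p, nucleotide_diversity(res$genotypes, res$popmap, p,
                                            stat_windows)))
      th_tabs <- lapply(pops, function(p)
        cbind(pop = p, watterson_theta(res$genotypes, res$popmap, p,
                                       stat_windows)))
      fst <- fst_distance_matrix(res$genotypes, res$popmap, stat_windows)
      list(pi = do.call(rbind, pi_tabs), theta = do.call(rbind, th_tabs),
           fst = fst)
    })
    res$stats <- st$value
    res$fst_before <- st$value$fst
    p1 <- out_path("pi.tsv"); p2 <- out_path("theta.tsv")
    p3 <- out_path("fst_matrix.tsv")
    utils::write.table(st$value$pi, p1, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    utils::write.table(st$value$theta, p2, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    utils::write.table(st$value$fst, p3, sep = "\t", quote = FALSE)
    record("stats", c(p1, p2, p3), st$elapsed)
  }

  if ("scan" %in% config$stages) {
    st <- t_stage("scan", {
      introgression_scan(res$genotypes, res$popmap, config$quartet,
                         window_size = config$window_size,
                         block_size = config$block_size,
                         z_threshold = config$z_threshold)
    })
    res$scan <- st$value
    p <- out_path("scan.tsv")
    utils::write.table(st$value, p, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    record("scan", p, st$elapsed)
  }

  if ("mask" %in% config$stages) {
    st <- t_stage("mask", {
      mask_introgressed(res$genotypes, res$scan,
                        z_threshold = config$z_threshold)
    })
    res$masked <- st$value$genotypes
    res$removed_windows <- st$value$removed
    p1 <- out_path("masked.vcf"); p2 <- out_path("removed_windows.bed")
    write_vcf(st$value$genotypes, p1)
    write_bed(st$value$removed[, c("chrom", "start", "end",
                                   "classification")], p2)
    record("mask", c(p1, p2), st$elapsed)
  }

  if ("restat" %in% config$stages) {
    st <- t_stage("restat", {
      fst_distance_matrix(res$masked, res$popmap, stat_windows)
    })
    res$fst_after <- st$value
    p <- out_path("fst_matrix_masked.tsv")
    utils::write.table(st$value, p, sep = "\t", quote = FALSE)
    record("restat", p, st$elapsed)
  }

  if ("tree" %in% config$stages) {
    st <- t_stage("tree", {
      gm <- if (!is.null(res$masked)) res$masked else res$genotypes
      do.call(bootstrap_support,
              c(list(gm, res$popmap, window_size = config$stat_window_size,
                     seed = stage_seed(config, "tree")),
                config$tree_params))
    })
    res$tree <- st$value
    p1 <- out_path("nj_tree.nwk"); p2 <- out_path("consensus_tree.nwk")
    write_newick(st$value$tree, p1)
    write_newick(st$value$consensus, p2)
    record("tree", c(p1, p2), st$elapsed)
  }

  mp <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, pretty = TRUE)
  res$manifest <- manifest
  res
}

#' Compare masked and unmasked pipeline results
#'
#' Reports, from a [run_pipeline()] result that ran the scan/mask/restat
#' stages: the per-pair Fst change after masking, removed-window counts by
#' scan classification, and (when trees for both states are supplied) the
#' Robinson-Foulds distance between them.
#'
#' @param run a [run_pipeline()] result (needs `fst_before`, `fst_after`,
#'   `scan`).
#' @param tree_before,tree_after optional `phylo` trees built from the
#'   unmasked and masked data.
#' @return list with `fst_delta` (matrix after - before), `removed_counts`
#'   (by classification), `n_removed`, and `rf_distance` (or NA).
#' @export
compare_masked_unmasked <- function(run, tree_before = NULL,
                                    tree_after = NULL) {
  if (is.null(run$fst_before) || is.null(run$fst_after) || is.null(run$scan)) {
    stop("run must contain fst_before, fst_after and scan results")
  }
  common <- intersect(rownames(run$fst_before), rownames(run$fst_after))
  delta <- run$fst_after[common, common] - run$fst_before[common, common]
  rem <- if (!is.null(run$removed_windows)) run$removed_windows else
    run$scan[run$scan$classification %in% c("into_Z", "into_Y"), ]
  removed_counts <- table(factor(rem$classification,
                                 levels = c("into_Z", "into_Y")))
  rf <- if (!is.null(tree_before) && !is.null(tree_after)) {
    robinson_foulds(tree_before, tree_after)
  } else NA_real_
  list(fst_delta = delta,
       removed_counts = removed_counts,
       n_removed = nrow(rem),
       rf_distance = rf)
}
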