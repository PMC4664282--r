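#' Pipeline configuration
#'
#' Collects every stage parameter of the end-to-end synthetic analysis
#' (simulate -> phenotypes -> haplotype probabilities -> scan -> report,
#' with optional DAM emulation and CNV stages) into one validated, list-like
#' object. A config round-trips losslessly through YAML
#' ([write_pipeline_config()] / [read_pipeline_config()]), and every random
#' stage draws from the single `seed`, so identical configs give identical
#' outputs.
#'
#' @param seed Master integer seed for all randomness.
#' @param n_rils Number of RILs to simulate.
#' @param panel Panel label.
#' @param breakpoint_rate,error_rate Mosaic and genotyping parameters of
#'   [simulate_panel()].
#' @param qtl List describing planted QTL: parallel vectors `chrom`, `cm`,
#'   and list `effects`; optional `cnv` (see [qtl_spec()]). NULL for a null
#'   trait.
#' @param phenotype List of [sim_config()] overrides (mean, h2, line_sd,
#'   reps_mean, reps_sd).
#' @param use_hmm Infer founder probabilities from marker data with the HMM
#'   (TRUE) or use the true mosaic ancestry (FALSE, fast).
#' @param hmm List of [hmm_params()] overrides plus `grid_step`.
#' @param scan List: `n_perm`, `alpha`, `grid_step`.
#' @param dam List or NULL; when a list (fields `activity_rate`,
#'   `sampling_min`, `damaged_fraction`, `filter_window`,
#'   `filter_min_counts`, `max_lines`), phenotypes are round-tripped
#'   through simulated DAM monitor files for the first `max_lines` lines.
#' @param cnv_stage Run the CNV imputation/association/rescan stage (uses
#'   `qtl$cnv`).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1, n_rils = 200, panel = "pA",
                            breakpoint_rate = 0.15, error_rate = 0.005,
                            qtl = NULL, phenotype = list(),
                            use_hmm = FALSE, hmm = list(),
                            scan = list(n_perm = 100, alpha = 0.05,
                              grid_step = 0.5),
                            dam = NULL, cnv_stage = FALSE) {
  cfg <- list(seed = as.integer(seed), n_rils = n_rils, panel = panel,
    breakpoint_rate = breakpoint_rate, error_rate = error_rate,
    qtl = qtl, phenotype = phenotype, use_hmm = use_hmm, hmm = hmm,
    scan = utils::modifyList(list(n_perm = 100, alpha = 0.05, grid_step = 0.5),
      scan),
    dam = dam, cnv_stage = cnv_stage)
  if (cfg$cnv_stage && (is.null(cfg$qtl) || is.null(cfg$qtl$cnv))) {
    abort("`cnv_stage = TRUE` requires a `qtl$cnv` locus.")
  }
  structure(cfg, class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param config A `pipeline_config`.
#' @param path YAML file path.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

qtl_from_config_ <- function(qtl) {
  if (is.null(qtl)) return(NULL)
  qtl_spec(chrom = as.character(qtl$chrom), cm = as.numeric(qtl$cm),
    effects = lapply(qtl$effects, as.numeric), cnv = qtl$cnv)
}

#' Run the end-to-end synthetic mapping pipeline
#'
#' Executes the configured stages in order — panel simulation, phenotype
#' simulation (optionally routed through DAM monitor emulation and lifespan
#' extraction), founder-probability construction (HMM or true mosaic),
#' genome scan with permutation threshold, peak calling, reporting, and the
#' optional CNV stage — writing the standard tabular artifacts plus a
#' provenance manifest into `out_dir`. Identical configs give identical
#' outputs.
#'
#' @param config A [pipeline_config()] or path to its YAML form.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the in-memory stage results (`sim`,
#'   `phenotypes`, `line_means`, `probs`, `scan`, `perm`, `peaks`,
#'   `report`, and when enabled `cnv`).
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- read_pipeline_config(config)
  if (!inherits(config, "pipeline_config")) {
    abort("`config` must be a pipeline_config or a YAML path.")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  t0 <- Sys.time()
  timings <- list()
  tick <- function(stage, expr) {
    s <- Sys.time()
    out <- force(expr)
    timings[[stage]] <<- round(as.numeric(Sys.time() - s, units = "secs"), 3)
    inform(sprintf("[%s] done in %.2fs", stage, timings[[stage]]))
    out
  }

  sim <- tick("simulate", simulate_panel(config$n_rils,
    breakpoint_rate = config$breakpoint_rate, error_rate = config$error_rate,
    panel = config$panel, seed = config$seed))
  readr::write_tsv(sim$panel$map, file.path(out_dir, "marker_map.tsv"))
  readr::write_tsv(
    dplyr::bind_cols(sim$panel$map[c("chrom", "cm", "bp")],
      as_tibble(sim$panel$alleles)),
    file.path(out_dir, "founder_alleles.tsv")
  )
  readr::write_tsv(sim$mosaics, file.path(out_dir, "mosaic_segments.tsv"))

  qtl <- qtl_from_config_(config$qtl)
  pheno_cfg <- do.call(sim_config,
    utils::modifyList(list(seed = config$seed + 1L), config$phenotype))
  phenos <- tick("phenotypes", simulate_phenotypes(sim, qtl, pheno_cfg))

  if (!is.null(config$dam)) {
    d <- utils::modifyList(
      list(activity_rate = 5, sampling_min = 1, damaged_fraction = 0,
        filter_window = 2, filter_min_counts = 5, max_lines = 20),
      config$dam)
    keep <- sim$lines$ril[seq_len(min(d$max_lines, nrow(sim$lines)))]
    sub <- phenos[phenos$Genotype %in% keep, ]
    streams <- simulate_dam_streams(sub$CaffeineResistance,
      sampling_min = d$sampling_min, activity_rate = d$activity_rate,
      damaged_fraction = d$damaged_fraction, seed = config$seed + 2L)
    dam_dir <- file.path(out_dir, "dam")
    dir.create(dam_dir, showWarnings = FALSE)
    calls <- purrr::map_dfr(seq_along(streams$monitors), function(m) {
      write_dam(streams$monitors[[m]],
        file.path(dam_dir, sprintf("Monitor%02d.txt", m)))
      rec <- read_dam(file.path(dam_dir, sprintf("Monitor%02d.txt", m)))
      dplyr::mutate(
        extract_lifespans(rec, filter_window = d$filter_window,
          filter_min_counts = d$filter_min_counts),
        monitor = m)
    })
    cmap <- dplyr::mutate(streams$channel_map, line = sub$Genotype[.data$fly])
    dam_means <- summarize_lines(calls, cmap)
    readr::write_csv(dam_means, file.path(out_dir, "dam_line_means.csv"))
    timings[["dam"]] <- NA
  }

  readr::write_csv(phenos, file.path(out_dir, "phenotypes.csv"))
  lm_tab <- line_means(phenos)

  probs <- tick("probs", if (isTRUE(config$use_hmm)) {
    hp <- do.call(hmm_params,
      config$hmm[setdiff(names(config$hmm), "grid_step")])
    infer_additive(sim$markers, sim$panel, hp,
      grid_step = config$hmm$grid_step %||% config$scan$grid_step)
  } else {
    true_additive(sim, grid_step = config$scan$grid_step)
  })

  scan <- tick("scan", genome_scan(lm_tab, probs))
  perm <- tick("permutations", permutation_threshold(lm_tab, probs,
    n_perm = config$scan$n_perm, alpha = config$scan$alpha,
    seed = config$seed + 3L))
  peaks <- peaks_and_intervals(scan, perm)
  write_scan_tsv(scan, file.path(out_dir, "scan.tsv"))

  vc <- variance_components_h2(phenos)
  report <- qtl_report(peaks, h2_mean = vc$h2_line, n = attr(scan, "n"))
  readr::write_tsv(report, file.path(out_dir, "qtl_report.tsv"))

  cnv_out <- NULL
  if (isTRUE(config$cnv_stage)) {
    cnv_out <- tick("cnv", {
      cnv <- qtl$cnv
      grid_i <- which.min(abs(probs$map$cm - cnv$cm) +
        ifelse(probs$map$chrom == cnv$chrom, 0, Inf))
      calls_cnv <- tibble(
        line = probs$lines,
        founder = hard_call(probs$probs[, , grid_i])
      )
      founder_cnv <- setNames(
        as.integer(sim$panel$founders %in% cnv$dup_founders),
        sim$panel$founders)
      status <- impute_ril_cnv(calls_cnv, founder_cnv)
      readr::write_tsv(
        tibble(RIL = status$line, DuplicationStatus = status$status),
        file.path(out_dir, "cnv_status.tsv"))
      list(status = status,
        test = cnv_effect_test(lm_tab, status),
        adjusted_scan = covariate_adjusted_scan(lm_tab, probs, status))
    })
    write_scan_tsv(cnv_out$adjusted_scan,
      file.path(out_dir, "scan_cnv_adjusted.tsv"))
  }

  manifest <- list(
    package = "mppscan",
    version = as.character(utils::packageVersion("mppscan")),
    config_hash = rlang::hash(unclass(config)),
    seed = config$seed,
    n_lines_scanned = attr(scan, "n"),
    threshold = perm$threshold,
    n_qtl = nrow(peaks),
    stage_seconds = timings,
    elapsed_seconds = round(as.numeric(Sys.time() - t0, units = "secs"), 3)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
    auto_unbox = TRUE, pretty = TRUE)

  invisible(list(sim = sim, phenotypes = phenos, line_means = lm_tab,
    probs = probs, scan = scan, perm = perm, peaks = peaks,
    report = report, cnv = cnv_out, manifest = manifest))
}
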