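#' Run configuration for the two-stage analysis pipeline
#'
#' Bundles all file paths, thresholds and the seed driving a full run, with
#' validation up front so a misconfigured run fails before any computation.
#' Configurations round-trip losslessly through YAML via [read_run_config()]
#' and [write_run_config()].
#'
#' @param panels_dir Directory of per-metabolite exposure TSVs.
#' @param outcome_path Primary-outcome summary-statistics TSV.
#' @param ld_path Optional LD matrix TSV (`NULL` to treat instruments as
#'   independent).
#' @param catalog_path Phenotype catalog TSV.
#' @param phenome_dir Directory of per-phecode outcome TSVs.
#' @param out_dir Output directory.
#' @param p_threshold,r2_clump,window_kb Instrument-selection controls
#'   (defaults 5e-8, 0.1, 500).
#' @param min_r2,min_snps Panel QC thresholds (defaults 0.005, 3).
#' @param alpha,sens_alpha Stage significance levels (defaults 0.05).
#' @param target_rr Primary-outcome risk ratio for stage-2 rescaling
#'   (default 0.90).
#' @param min_cases Catalog case-count filter (default 500).
#' @param n_boot Weighted-median bootstrap replicates (default 1000).
#' @param seed Integer seed (default 1).
#' @param scenario Named list of synthetic-scenario parameters consumed by
#'   [pipeline_simulate()].
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(panels_dir = "panels", outcome_path = "outcome.tsv",
                       ld_path = NULL, catalog_path = "catalog.tsv",
                       phenome_dir = "phenome", out_dir = "results",
                       p_threshold = 5e-8, r2_clump = 0.1, window_kb = 500,
                       min_r2 = 0.005, min_snps = 3, alpha = 0.05,
                       sens_alpha = 0.05, target_rr = 0.90, min_cases = 500,
                       n_boot = 1000, seed = 1, scenario = list()) {
  cfg <- list(
    panels_dir = panels_dir, outcome_path = outcome_path, ld_path = ld_path,
    catalog_path = catalog_path, phenome_dir = phenome_dir, out_dir = out_dir,
    p_threshold = p_threshold, r2_clump = r2_clump, window_kb = window_kb,
    min_r2 = min_r2, min_snps = min_snps, alpha = alpha,
    sens_alpha = sens_alpha, target_rr = target_rr, min_cases = min_cases,
    n_boot = n_boot, seed = as.integer(seed), scenario = scenario
  )
  validate_run_config(cfg)
}

validate_run_config <- function(cfg) {
  chk <- function(ok, msg) if (!ok) abort(msg, class = "metabomr_config_error")
  chk(cfg$p_threshold > 0 && cfg$p_threshold < 1, "p_threshold must lie in (0,1)")
  chk(cfg$r2_clump >= 0 && cfg$r2_clump <= 1, "r2_clump must lie in [0,1]")
  chk(cfg$window_kb > 0, "window_kb must be positive")
  chk(cfg$min_r2 >= 0 && cfg$min_r2 < 1, "min_r2 must lie in [0,1)")
  chk(cfg$min_snps >= 1, "min_snps must be at least 1")
  chk(cfg$alpha > 0 && cfg$alpha < 1, "alpha must lie in (0,1)")
  chk(cfg$sens_alpha > 0 && cfg$sens_alpha < 1, "sens_alpha must lie in (0,1)")
  chk(cfg$target_rr > 0 && cfg$target_rr < 1, "target_rr must lie in (0,1)")
  chk(cfg$min_cases >= 0, "min_cases must be nonnegative")
  chk(cfg$n_boot >= 2, "n_boot must be at least 2")
  structure(cfg, class = "run_config")
}

#' @rdname run_config
#' @param path YAML file path.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) {
    abort(glue::glue("config file not found: {path}"),
          class = "metabomr_config_error")
  }
  raw <- yaml::read_yaml(path)
  do.call(run_config, raw)
}

#' @rdname run_config
#' @param config A `run_config` object.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

log_lines <- function(path, lines) {
  writeLines(lines, path)
  invisible(path)
}

default_scenario <- function() {
  list(
    n_metabolites = 20, n_causal_metabolites = 2, metabolite_effect = 0.2,
    n_phenotypes = 50, n_causal_phenotypes = 3,
    phenotype_effect_range = c(0.1, 0.3),
    n_sex_specific = 2, n_small = 3, n_redundant = 1,
    n_instruments = 50, n_exposure = 24925, n_outcome = 228951,
    case_fraction = 122977 / 228951, exposure_r2_total = 0.10
  )
}

#' Write a complete synthetic input bundle for the two-stage pipeline
#'
#' Simulates per-metabolite exposure panels against a shared primary outcome
#' (a configurable number of metabolites carrying true causal effects), plus
#' a phenotype catalog and per-phecode outcome tables, and writes everything
#' in the TSV dialects the pipeline readers consume, together with
#' ground-truth tables for recovery checks.
#'
#' @param config A [run_config()]; its `scenario` entries override the
#'   default scenario and its `seed` drives all randomness.
#' @param dir Directory to write the bundle into; default the config paths'
#'   common parent, created if needed.
#' @return The config, updated to point at the written files, invisibly.
#' @export
pipeline_simulate <- function(config, dir = ".") {
  stopifnot(inherits(config, "run_config"))
  sc <- modifyList(default_scenario(), config$scenario)
  panels_dir <- file.path(dir, config$panels_dir)
  phenome_dir <- file.path(dir, config$phenome_dir)
  for (d in c(dir, panels_dir, phenome_dir)) {
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
  }

  truth_tmpl <- simulation_truth(
    n_instruments = sc$n_instruments, n_exposure = sc$n_exposure,
    n_outcome = sc$n_outcome, case_fraction = sc$case_fraction,
    exposure_r2_total = sc$exposure_r2_total, seed = config$seed
  )

  with_local_seed(config$seed, {
    met_ids <- sprintf("metab_%03d", seq_len(sc$n_metabolites))
    causal <- sample(met_ids, sc$n_causal_metabolites)
    outcome_rows <- list()
    truth_rows <- list()
    vmeta <- vector("list", length(met_ids))
    for (i in seq_along(met_ids)) {
      tr <- truth_tmpl
      tr$true_beta <- if (met_ids[i] %in% causal) sc$metabolite_effect else 0
      vm <- draw_variant_meta(tr, id_prefix = sprintf("rs%02d_", i))
      vmeta[[i]] <- vm
      write_summary_stats(exposure_table(vm, tr),
                          file.path(panels_dir, paste0(met_ids[i], ".tsv")))
      outcome_rows[[i]] <- outcome_table(vm, tr)
      truth_rows[[i]] <- tibble(trait_id = met_ids[i],
                                true_beta = tr$true_beta)
    }
    write_summary_stats(bind_rows(outcome_rows),
                        file.path(dir, config$outcome_path))
    readr::write_tsv(bind_rows(truth_rows),
                     file.path(dir, "truth_metabolites.tsv"), progress = FALSE)

    # phenome: outcome tables cover every metabolite panel's variants (as a
    # genome-wide phenotype GWAS would); each causal phenotype responds to
    # one causal metabolite
    cat_parts <- make_phenome_catalog(
      sc$n_phenotypes,
      list(n_sex_specific = sc$n_sex_specific, n_small = sc$n_small,
           n_redundant = sc$n_redundant),
      sc$n_causal_phenotypes
    )
    catalog <- cat_parts$catalog
    true_beta <- numeric(sc$n_phenotypes)
    driver <- rep(NA_character_, sc$n_phenotypes)
    true_beta[cat_parts$causal_idx] <-
      runif(sc$n_causal_phenotypes, sc$phenotype_effect_range[1],
            sc$phenotype_effect_range[2]) *
      sample(c(-1, 1), sc$n_causal_phenotypes, replace = TRUE)
    driver[cat_parts$causal_idx] <-
      sample(causal, sc$n_causal_phenotypes, replace = TRUE)
    readr::write_tsv(catalog, file.path(dir, config$catalog_path),
                     progress = FALSE)

    for (p in seq_len(sc$n_phenotypes)) {
      tabs <- purrr::map(seq_along(met_ids), function(i) {
        tr <- truth_tmpl
        tr$true_beta <- if (identical(driver[p], met_ids[i])) true_beta[p] else 0
        tr$n_outcome <- catalog$n_cases[p] + catalog$n_controls[p]
        tr$case_fraction <- catalog$n_cases[p] / tr$n_outcome
        outcome_table(vmeta[[i]], tr)
      })
      write_summary_stats(bind_rows(tabs),
                          file.path(phenome_dir,
                                    paste0(catalog$phecode[p], ".tsv")))
    }
    readr::write_tsv(tibble(phecode = catalog$phecode, true_beta = true_beta,
                            driver_metabolite = driver),
                     file.path(dir, "truth_phenome.tsv"), progress = FALSE)
  })
  write_run_config(config, file.path(dir, "run_config.yaml"))
  invisible(config)
}

read_panel_dir <- function(dir) {
  paths <- sort(list.files(dir, pattern = "\\.tsv$", full.names = TRUE))
  if (!length(paths)) {
    abort(glue::glue("no panel TSVs found in {dir}"),
          class = "metabomr_config_error")
  }
  panels <- purrr::map(paths, read_summary_stats)
  names(panels) <- tools::file_path_sans_ext(basename(paths))
  panels
}

#' Run the stage-1 metabolome-wide screen from files
#'
#' Reads every exposure panel, selects and quality-controls instruments,
#' screens the retained panels against the primary outcome, and writes the
#' result tables plus a log recording every threshold and count: panel
#' counts, the Bonferroni construction `alpha / M`, and the nominations.
#'
#' @param config A [run_config()].
#' @param dir Directory the input paths are relative to; default `"."`.
#' @return The `mr_screen` object (with an extra `qc` element), invisibly.
#'   Output files: `screen_summary.tsv`, `screen_results.tsv`,
#'   `exclusion_report.tsv`, `manhattan.tsv`, `screen_log.txt`.
#' @export
pipeline_screen <- function(config, dir = ".") {
  stopifnot(inherits(config, "run_config"))
  panels_dir <- file.path(dir, config$panels_dir)
  outcome_path <- file.path(dir, config$outcome_path)
  if (!dir.exists(panels_dir)) {
    abort(glue::glue("panels directory not found: {panels_dir}"),
          class = "metabomr_config_error")
  }
  out_dir <- file.path(dir, config$out_dir)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  panels <- read_panel_dir(panels_dir)
  outcome <- read_summary_stats(outcome_path, trait_type = "binary")
  ld <- if (!is.null(config$ld_path)) read_ld_matrix(file.path(dir, config$ld_path))

  selected <- purrr::map(panels, select_instruments, ld = ld,
                         p_threshold = config$p_threshold,
                         r2_clump = config$r2_clump,
                         window_kb = config$window_kb)
  stats <- purrr::imap(selected, function(inst, id) {
    n <- if (nrow(inst)) stats::median(inst$n) else 2 + config$min_snps
    instrument_stats(inst, n = n, trait_id = id)
  })
  qc <- qc_filter(bind_rows(stats), min_r2 = config$min_r2,
                  min_snps = config$min_snps)
  readr::write_tsv(qc, file.path(out_dir, "exclusion_report.tsv"),
                   progress = FALSE)
  retained_ids <- qc$trait_id[qc$status == "retained"]
  if (!length(retained_ids)) {
    abort("no panel survived instrument QC", class = "metabomr_data_error")
  }
  screen <- run_screen(selected[retained_ids], outcome, ld = ld,
                       alpha = config$alpha, sens_alpha = config$sens_alpha,
                       n_boot = config$n_boot, seed = config$seed)
  screen$qc <- qc
  readr::write_tsv(screen$summary, file.path(out_dir, "screen_summary.tsv"),
                   progress = FALSE)
  readr::write_tsv(screen$results, file.path(out_dir, "screen_results.tsv"),
                   progress = FALSE)
  readr::write_tsv(manhattan_data(screen), file.path(out_dir, "manhattan.tsv"),
                   progress = FALSE)
  for (id in screen$summary$trait_id[screen$summary$nominated]) {
    write_summary_stats(selected[[id]],
                        file.path(out_dir, paste0("nominated_", id, ".tsv")))
  }
  log_lines(file.path(out_dir, "screen_log.txt"), c(
    "stage 1: metabolome-wide screen",
    glue::glue("panels read: {length(panels)}"),
    glue::glue("panels retained after QC (M): {screen$m}"),
    glue::glue("panels excluded: {sum(qc$status == 'excluded')}"),
    glue::glue("p_threshold={config$p_threshold} r2_clump={config$r2_clump} ",
               "window_kb={config$window_kb} min_r2={config$min_r2} ",
               "min_snps={config$min_snps}"),
    glue::glue("bonferroni threshold: {config$alpha}/{screen$m} = {screen$threshold}"),
    glue::glue("sens_alpha={config$sens_alpha} n_boot={config$n_boot} seed={config$seed}"),
    glue::glue("bonferroni passes: {sum(screen$summary$passed_bonferroni)}"),
    glue::glue("nominated: {sum(screen$summary$nominated)} ",
               "({paste(screen$summary$trait_id[screen$summary$nominated], collapse = ', ')})")
  ))
  invisible(screen)
}

#' Run the stage-2 phenome-wide scan from files
#'
#' Uses the stage-1 nominations (instrument panels and IVW estimates written
#' by [pipeline_screen()]), the phenotype catalog and the per-phecode outcome
#' tables to run the phenome-wide scan, writing a results TSV with scaled
#' odds ratios, direction labels and chapter grouping, plus a log with the
#' threshold provenance. With zero nominated metabolites this is a graceful
#' no-op with a message.
#'
#' @param config A [run_config()].
#' @param dir Directory the input paths are relative to; default `"."`.
#' @return The `mr_phemr` object invisibly, or `NULL` when nothing was
#'   nominated. Output files: `phemr_summary.tsv`, `phemr_results.tsv`,
#'   `phemr_log.txt`.
#' @export
pipeline_phemr <- function(config, dir = ".") {
  stopifnot(inherits(config, "run_config"))
  out_dir <- file.path(dir, config$out_dir)
  screen_summary_path <- file.path(out_dir, "screen_summary.tsv")
  if (!file.exists(screen_summary_path)) {
    abort("stage-1 results not found; run pipeline_screen first",
          class = "metabomr_config_error")
  }
  ss <- readr::read_tsv(screen_summary_path, show_col_types = FALSE,
                        progress = FALSE)
  nominated <- ss[ss$nominated, , drop = FALSE]
  if (!nrow(nominated)) {
    inform("no metabolites nominated in stage 1; nothing to scan")
    return(invisible(NULL))
  }
  panels <- purrr::map(nominated$trait_id, function(id) {
    read_summary_stats(file.path(out_dir, paste0("nominated_", id, ".tsv")))
  })
  names(panels) <- nominated$trait_id
  catalog <- readr::read_tsv(file.path(dir, config$catalog_path),
                             show_col_types = FALSE, progress = FALSE)
  phen_dir <- file.path(dir, config$phenome_dir)
  paths <- list.files(phen_dir, pattern = "\\.tsv$", full.names = TRUE)
  outcomes <- purrr::map(paths, read_summary_stats, trait_type = "binary")
  names(outcomes) <- tools::file_path_sans_ext(basename(paths))
  ld <- if (!is.null(config$ld_path)) read_ld_matrix(file.path(dir, config$ld_path))

  phemr <- run_phemr(
    panels, outcomes,
    primary_estimates = tibble(trait_id = nominated$trait_id,
                               beta = nominated$ivw_beta),
    catalog = catalog, ld = ld, alpha = config$alpha,
    sens_alpha = config$sens_alpha, target_rr = config$target_rr,
    min_cases = config$min_cases, n_boot = config$n_boot, seed = config$seed
  )
  readr::write_tsv(phemr$summary, file.path(out_dir, "phemr_summary.tsv"),
                   progress = FALSE)
  readr::write_tsv(phemr$results, file.path(out_dir, "phemr_results.tsv"),
                   progress = FALSE)
  counts <- attr(filter_phenotypes(catalog, config$min_cases), "counts")
  log_lines(file.path(out_dir, "phemr_log.txt"), c(
    "stage 2: phenome-wide scan",
    glue::glue("nominated metabolites: {length(panels)} ",
               "({paste(names(panels), collapse = ', ')})"),
    glue::glue("catalog entries: {nrow(catalog)}; retained: {nrow(phemr$catalog)}"),
    paste(names(counts), counts, sep = "=", collapse = "; "),
    glue::glue("bonferroni denominator: {length(panels)} x {nrow(phemr$catalog)} ",
               "= {phemr$denominator}"),
    glue::glue("threshold: {config$alpha}/{phemr$denominator} = {phemr$threshold}"),
    glue::glue("target risk ratio: {config$target_rr}"),
    glue::glue("bonferroni passes: {sum(phemr$summary$passed_bonferroni)}"),
    glue::glue("passing sensitivity: {sum(phemr$summary$nominated)}")
  ))
  invisible(phemr)
}
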