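#' Filter a phenotype catalog for phenome-wide MR
#'
#' Drops sex-specific phenotypes, phenotypes with fewer than `min_cases`
#' cases, and phenotypes marked redundant of another entry, reporting counts
#' per exclusion reason.
#'
#' @param catalog Tibble of phenotype entries: `phecode`, `label`,
#'   `icd_chapter`, `n_cases`, `n_controls`, `sex_specific`, `redundant_of`.
#' @param min_cases Strict lower bound on cases; entries with
#'   `n_cases < min_cases` are excluded (default 500, so 500 cases is kept).
#' @return The retained catalog tibble, with attributes `excluded` (tibble
#'   `phecode`, `reason`) and `counts` (named integer vector per reason).
#' @export
filter_phenotypes <- function(catalog, min_cases = 500) {
  catalog <- as_tibble(catalog)
  reason <- case_when(
    catalog$sex_specific ~ "sex-specific",
    catalog$n_cases < min_cases ~ glue::glue("cases < {min_cases}"),
    !is.na(catalog$redundant_of) ~ "redundant",
    TRUE ~ NA_character_
  )
  keep <- is.na(reason)
  out <- catalog[keep, , drop = FALSE]
  excluded <- tibble(phecode = catalog$phecode[!keep],
                     reason = as.character(reason[!keep]))
  attr(out, "excluded") <- excluded
  attr(out, "counts") <- c(table(excluded$reason),
                           retained = sum(keep))
  out
}

#' Rescale a per-SD estimate to a fixed primary-risk-reduction unit
#'
#' Phenome-wide estimates are reported per change in metabolite level that
#' yields a `1 - target_rr` reduction in primary-outcome risk: the required
#' shift is `delta = log(target_rr) / beta_primary` SD of the metabolite, so
#' the scaled log-OR for a secondary disease is `beta_disease * delta` with
#' standard error `se_disease * |delta|`. Applying the scaling to the primary
#' outcome itself returns an odds ratio of exactly `target_rr`. Side effects
#' with scaled OR above 1 are deleterious (the intervention raises that
#' disease's risk); below 1 beneficial.
#'
#' @param beta_disease,se_disease Per-SD log-OR and SE for the secondary
#'   disease (vectorised).
#' @param beta_primary Per-SD log-OR of the metabolite on the primary
#'   outcome; must be nonzero.
#' @param target_rr Target primary-outcome risk ratio; default 0.90 (a 10%
#'   risk reduction).
#' @param null_direction Label used when the scaled OR is exactly 1; default
#'   `"beneficial"`.
#' @return Tibble with `delta`, `scaled_beta`, `scaled_se`, `scaled_or`,
#'   `scaled_ci_low`, `scaled_ci_high`, `direction`.
#' @examples
#' rescale_to_risk_reduction(0.2, 0.05, beta_primary = log(1.24))
#' @export
rescale_to_risk_reduction <- function(beta_disease, se_disease, beta_primary,
                                      target_rr = 0.90,
                                      null_direction = "beneficial") {
  if (beta_primary == 0) {
    abort("primary-outcome effect is zero: scaling undefined",
          class = "metabomr_data_error")
  }
  delta <- log(target_rr) / beta_primary
  scaled_beta <- beta_disease * delta
  scaled_se <- se_disease * abs(delta)
  scaled_or <- exp(scaled_beta)
  tibble(
    delta = delta, scaled_beta = scaled_beta, scaled_se = scaled_se,
    scaled_or = scaled_or,
    scaled_ci_low = exp(scaled_beta - Z95 * scaled_se),
    scaled_ci_high = exp(scaled_beta + Z95 * scaled_se),
    direction = case_when(scaled_or > 1 ~ "deleterious",
                          scaled_or < 1 ~ "beneficial",
                          TRUE ~ null_direction)
  )
}

#' Stage-2 phenome-wide MR scan
#'
#' For every nominated metabolite and every phenotype retained by
#' [filter_phenotypes()], harmonizes the metabolite's instruments with the
#' phenotype GWAS, runs the estimator battery on the per-SD scale, applies
#' the stage-2 Bonferroni threshold `alpha / (n_metabolites * n_phenotypes)`
#' to the IVW p-value, applies the same sensitivity-concordance rule as
#' stage 1, and rescales every estimate to the `1 - target_rr`
#' primary-risk-reduction unit. Pairs with too few usable instruments are
#' flagged unestimable but still count in the multiplicity denominator, which
#' is fixed by the study design before estimation.
#'
#' @param panels Named list of instrument tibbles for the nominated
#'   metabolites.
#' @param outcomes Named list of phenotype association tibbles keyed by
#'   phecode (a superset of the retained catalog is fine).
#' @param primary_estimates Tibble `trait_id`, `beta`: each metabolite's
#'   stage-1 IVW effect on the primary outcome, used for the rescaling.
#' @param catalog Phenotype catalog tibble (filtered internally).
#' @param ld Optional LD matrix for proxy substitution.
#' @param alpha Family-wise error rate; default 0.05.
#' @param sens_alpha Nominal level for the sensitivity battery; default 0.05.
#' @param target_rr Target primary-outcome risk ratio; default 0.90.
#' @param min_cases Passed to [filter_phenotypes()].
#' @param n_boot,seed Weighted-median bootstrap controls.
#' @return An object of class `mr_phemr` with per-pair `summary` (wide, with
#'   scaled ORs and direction), long `results`, the retained `catalog`,
#'   `threshold` and `denominator`.
#' @export
run_phemr <- function(panels, outcomes, primary_estimates, catalog,
                      ld = NULL, alpha = 0.05, sens_alpha = 0.05,
                      target_rr = 0.90, min_cases = 500,
                      n_boot = 1000, seed = 1) {
  stopifnot(is.list(panels), length(panels) >= 1)
  met_ids <- names(panels) %||% paste0("metabolite_", seq_along(panels))
  if (!all(met_ids %in% primary_estimates$trait_id)) {
    abort("every metabolite needs a primary-outcome estimate",
          class = "metabomr_data_error")
  }
  retained <- filter_phenotypes(catalog, min_cases = min_cases)
  missing_out <- setdiff(retained$phecode, names(outcomes))
  if (length(missing_out)) {
    abort(glue::glue("no outcome table for phecode(s): ",
                     "{paste(head(missing_out, 5), collapse = ', ')}"),
          class = "metabomr_data_error")
  }
  denominator <- length(met_ids) * nrow(retained)
  threshold <- bonferroni_threshold(alpha, denominator)

  pair_rows <- list(); long_rows <- list()
  for (mi in seq_along(met_ids)) {
    met <- met_ids[mi]
    beta_primary <- primary_estimates$beta[primary_estimates$trait_id == met][1]
    for (pi in seq_len(nrow(retained))) {
      code <- retained$phecode[pi]
      harm <- harmonize(panels[[mi]], outcomes[[code]], ld = ld)
      if (nrow(harm) < 3) {
        row <- unestimable_row()
      } else {
        fit <- mr_fit(harm, n_boot = n_boot, seed = seed,
                      exposure = met, outcome = code)
        row <- fit_wide_row(fit)
        long_rows[[length(long_rows) + 1]] <-
          mutate(fit$estimates, metabolite_id = met, phecode = code,
                 .before = 1)
      }
      pair_rows[[length(pair_rows) + 1]] <- bind_cols(
        tibble(metabolite_id = met, phecode = code,
               label = retained$label[pi],
               icd_chapter = retained$icd_chapter[pi]),
        row
      )
    }
  }
  wide <- bind_rows(pair_rows)
  wide <- concordance_flags(wide, threshold, sens_alpha)
  scaled <- purrr::map(seq_len(nrow(wide)), function(i) {
    if (!wide$estimable[i]) {
      return(tibble(delta = NA_real_, scaled_beta = NA_real_,
                    scaled_se = NA_real_, scaled_or = NA_real_,
                    scaled_ci_low = NA_real_, scaled_ci_high = NA_real_,
                    direction = NA_character_))
    }
    bp <- primary_estimates$beta[primary_estimates$trait_id ==
                                   wide$metabolite_id[i]][1]
    rescale_to_risk_reduction(wide$ivw_beta[i], wide$ivw_se[i], bp, target_rr)
  })
  wide <- bind_cols(wide, bind_rows(scaled))
  wide <- wide %>%
    group_by(.data$metabolite_id) %>%
    arrange(.data$ivw_pval, .by_group = TRUE) %>%
    ungroup()

  long <- bind_rows(long_rows)
  structure(
    list(summary = wide, results = long, catalog = retained,
         threshold = threshold, denominator = denominator,
         alpha = alpha, target_rr = target_rr,
         metabolites = met_ids),
    class = "mr_phemr"
  )
}

#' @export
print.mr_phemr <- function(x, ...) {
  cat("Phenome-wide MR scan:", length(x$metabolites), "metabolite(s) x",
      nrow(x$catalog), "phenotypes\n")
  cat("threshold", format(x$threshold, digits = 3),
      paste0("(", x$alpha, "/", x$denominator, ")"), "\n")
  cat(sum(x$summary$passed_bonferroni), "Bonferroni-significant pair(s),",
      sum(x$summary$nominated), "surviving sensitivity analysis\n")
  invisible(x)
}

#' @rdname run_phemr
#' @param x An `mr_phemr` object.
#' @param ... Unused.
#' @export
tidy.mr_phemr <- function(x, ...) x$summary

#' @rdname run_phemr
#' @export
glance.mr_phemr <- function(x, ...) {
  tibble(n_metabolites = length(x$metabolites),
         n_phenotypes = nrow(x$catalog),
         denominator = x$denominator, threshold = x$threshold,
         target_rr = x$target_rr,
         n_bonferroni = sum(x$summary$passed_bonferroni),
         n_nominated = sum(x$summary$nominated))
}
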