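#' Bonferroni-corrected significance threshold
#'
#' @param alpha Family-wise error rate; default 0.05.
#' @param m Number of tests.
#' @return `alpha / m`.
#' @examples
#' bonferroni_threshold(0.05, 112)   # stage-1 style: 4.46e-4
#' bonferroni_threshold(0.05, 1358)  # stage-2 style: 3.68e-5
#' @export
bonferroni_threshold <- function(alpha = 0.05, m) {
  if (m < 1) abort("need at least one test", class = "metabomr_parameter_error")
  alpha / m
}

# one wide row per trait from an mr_fit (NA row when unestimable)
fit_wide_row <- function(fit) {
  e <- fit$estimates
  pick <- function(method, col) {
    v <- e[[col]][e$method == method | (method == "IVW" & grepl("^IVW", e$method))]
    if (length(v)) v[1] else NA_real_
  }
  tibble(
    n_snps = nrow(fit$data),
    ivw_model = e$method[grepl("^IVW", e$method)][1],
    ivw_beta = pick("IVW", "beta"), ivw_se = pick("IVW", "se"),
    ivw_pval = pick("IVW", "pval"),
    q_stat = pick("IVW", "q_stat"), q_pval = pick("IVW", "q_pval"),
    wm_beta = pick("weighted_median", "beta"),
    wm_se = pick("weighted_median", "se"),
    wm_pval = pick("weighted_median", "pval"),
    raps_beta = pick("MR_RAPS", "beta"), raps_se = pick("MR_RAPS", "se"),
    raps_pval = pick("MR_RAPS", "pval"),
    egger_beta = pick("MR_Egger", "beta"),
    egger_intercept = pick("MR_Egger", "egger_intercept"),
    egger_intercept_pval = pick("MR_Egger", "egger_intercept_pval"),
    estimable = TRUE
  )
}

unestimable_row <- function() {
  row <- fit_wide_row(list(estimates = mr_est_row("none", NA_real_, NA_real_, 0),
                           data = tibble()))
  row$n_snps <- 0L
  row$ivw_model <- NA_character_
  row$estimable <- FALSE
  row
}

concordance_flags <- function(wide, threshold, sens_alpha, egger_alpha = 0.05) {
  wide$passed_bonferroni <- !is.na(wide$ivw_pval) & wide$ivw_pval < threshold
  sgn <- sign(wide$ivw_beta)
  wide$passed_sensitivity <-
    !is.na(wide$wm_pval) & wide$wm_pval < sens_alpha &
    !is.na(wide$raps_pval) & wide$raps_pval < sens_alpha &
    sign(wide$wm_beta) == sgn & sign(wide$raps_beta) == sgn &
    !is.na(wide$egger_intercept_pval) & wide$egger_intercept_pval >= egger_alpha
  wide$passed_sensitivity[is.na(wide$passed_sensitivity)] <- FALSE
  wide$nominated <- wide$passed_bonferroni & wide$passed_sensitivity
  wide
}

#' Apply the sensitivity-concordance nomination rule
#'
#' A trait passing the stage-1 Bonferroni threshold by IVW is nominated as a
#' putative causal mediator only when the robust estimators concur: weighted
#' median and MR-RAPS both significant at `sens_alpha` with the same effect
#' sign as IVW, and the MR-Egger intercept showing no evidence of directional
#' pleiotropy (two-sided intercept p of at least 0.05).
#'
#' @param summary_tbl A wide per-trait summary (e.g. `summary(screen)` rows)
#'   with `ivw_pval`, `ivw_beta`, `wm_*`, `raps_*`, `egger_intercept_pval`.
#' @param threshold Bonferroni threshold applied to the IVW p-value.
#' @param sens_alpha Nominal level for the robust estimators; default 0.05.
#' @return The summary with `passed_bonferroni`, `passed_sensitivity`,
#'   `nominated` columns recomputed.
#' @export
sensitivity_concordance <- function(summary_tbl, threshold, sens_alpha = 0.05) {
  concordance_flags(as_tibble(summary_tbl), threshold, sens_alpha)
}

#' Stage-1 metabolome-wide MR screen
#'
#' Runs the full estimator battery (IVW with automatic model choice, weighted
#' median, MR-RAPS, MR-Egger) for every exposure panel against the primary
#' outcome, applies the Bonferroni threshold `alpha / M` (with `M` the number
#' of panels screened), and nominates traits through the
#' sensitivity-concordance rule. Panels losing all instruments in
#' harmonization are flagged unestimable but still count in `M`.
#'
#' @param panels Named list of instrument association tibbles, one per
#'   exposure trait (names are trait ids).
#' @param outcome Outcome summary-statistics tibble.
#' @param ld Optional LD matrix enabling proxy substitution.
#' @param alpha Family-wise error rate for the screen; default 0.05.
#' @param sens_alpha Nominal level for the sensitivity battery; default 0.05.
#' @param n_boot,seed Weighted-median bootstrap controls.
#' @param pathway_groups Optional named character vector mapping trait ids to
#'   pathway labels used for plotting.
#' @return An object of class `mr_screen`: per-trait wide `summary` (sorted
#'   by IVW p), long `results` (trait by method), `threshold`, `m`, `alpha`.
#' @export
run_screen <- function(panels, outcome, ld = NULL, alpha = 0.05,
                       sens_alpha = 0.05, n_boot = 1000, seed = 1,
                       pathway_groups = NULL) {
  stopifnot(is.list(panels), length(panels) >= 1)
  ids <- names(panels) %||% paste0("trait_", seq_along(panels))
  m <- length(panels)
  threshold <- bonferroni_threshold(alpha, m)

  fits <- vector("list", m)
  rows <- vector("list", m)
  for (i in seq_len(m)) {
    harm <- harmonize(panels[[i]], outcome, ld = ld)
    if (nrow(harm) < 3) {
      rows[[i]] <- unestimable_row()
      next
    }
    fit <- mr_fit(harm, n_boot = n_boot, seed = seed, exposure = ids[i])
    fits[[i]] <- fit
    rows[[i]] <- fit_wide_row(fit)
  }
  wide <- bind_rows(rows)
  wide <- bind_cols(tibble(trait_id = ids), wide)
  wide$pathway_group <- if (is.null(pathway_groups)) NA_character_ else
    unname(pathway_groups[wide$trait_id])
  wide <- concordance_flags(wide, threshold, sens_alpha)
  wide <- wide[order(wide$ivw_pval, wide$trait_id), , drop = FALSE]

  long <- purrr::imap(fits, function(f, i) {
    if (is.null(f)) return(NULL)
    mutate(f$estimates, trait_id = ids[i], .before = 1)
  })
  structure(
    list(summary = wide, results = bind_rows(long), fits = fits,
         threshold = threshold, m = m, alpha = alpha,
         sens_alpha = sens_alpha),
    class = "mr_screen"
  )
}

#' @export
print.mr_screen <- function(x, ...) {
  cat("Metabolome-wide MR screen:", x$m, "panels, threshold",
      format(x$threshold, digits = 3), paste0("(", x$alpha, "/", x$m, ")\n"))
  cat(sum(x$summary$nominated), "trait(s) nominated\n")
  invisible(x)
}

#' @rdname run_screen
#' @param x,object An `mr_screen` object.
#' @param ... Unused.
#' @export
tidy.mr_screen <- function(x, ...) x$results

#' @rdname run_screen
#' @export
glance.mr_screen <- function(x, ...) {
  tibble(m = x$m, alpha = x$alpha, threshold = x$threshold,
         n_estimable = sum(x$summary$estimable),
         n_bonferroni = sum(x$summary$passed_bonferroni),
         n_nominated = sum(x$summary$nominated))
}

#' Manhattan-plot data export for a screen
#'
#' @param screen An `mr_screen` object.
#' @return Tibble with `trait_id`, `pathway_group`, `neg_log10_p` (IVW) and
#'   the `threshold_line` value, ready for plotting.
#' @export
manhattan_data <- function(screen) {
  stopifnot(inherits(screen, "mr_screen"))
  s <- screen$summary
  tibble(trait_id = s$trait_id,
         pathway_group = s$pathway_group,
         neg_log10_p = -log10(s$ivw_pval),
         threshold_line = -log10(screen$threshold))
}
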