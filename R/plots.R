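#' Forest plot of estimator results for one exposure-outcome pair
#'
#' @param object An `mr_fit` object.
#' @param ... Unused.
#' @return A ggplot object: point estimates with 95% CIs per method.
#' @export
autoplot.mr_fit <- function(object, ...) {
  e <- object$estimates
  ggplot2::ggplot(e, ggplot2::aes(x = .data$beta, y = .data$method)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$ci_low, xmax = .data$ci_high), height = 0.15) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "causal estimate (log scale per SD exposure)",
                  y = NULL,
                  title = if (!is.na(object$exposure))
                    paste(object$exposure, "→", object$outcome) else NULL) +
    ggplot2::theme_minimal()
}

#' Manhattan-style plot of a metabolome-wide screen
#'
#' @param object An `mr_screen` object.
#' @param ... Unused.
#' @return A ggplot object: one point per trait at its IVW -log10 p,
#'   coloured by pathway group when available, with the Bonferroni threshold
#'   as a dashed line.
#' @export
autoplot.mr_screen <- function(object, ...) {
  d <- manhattan_data(object)
  d$trait_id <- factor(d$trait_id, levels = d$trait_id)
  aes <- if (all(is.na(d$pathway_group))) {
    ggplot2::aes(x = .data$trait_id, y = .data$neg_log10_p)
  } else {
    ggplot2::aes(x = .data$trait_id, y = .data$neg_log10_p,
                 colour = .data$pathway_group)
  }
  ggplot2::ggplot(d, aes) +
    ggplot2::geom_point(size = 1.8) +
    ggplot2::geom_hline(yintercept = d$threshold_line[1],
                        linetype = "dashed", colour = "red") +
    ggplot2::labs(x = NULL, y = expression(-log[10](italic(p))),
                  colour = "pathway") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}

#' Side-effect profile plot for a phenome-wide MR scan
#'
#' Scaled odds ratios per disease, grouped by ICD chapter, with the unit line
#' as the deleterious/beneficial midline: associations above the line are
#' deleterious side effects of the intervention, below it beneficial.
#'
#' @param object An `mr_phemr` object.
#' @param significant_only Plot only Bonferroni-significant pairs; default
#'   `FALSE`.
#' @param ... Unused.
#' @return A ggplot object faceted by metabolite.
#' @export
autoplot.mr_phemr <- function(object, significant_only = FALSE, ...) {
  d <- object$summary[object$summary$estimable, , drop = FALSE]
  if (significant_only) d <- d[d$passed_bonferroni, , drop = FALSE]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$icd_chapter, y = .data$scaled_or,
                                  colour = .data$icd_chapter)) +
    ggplot2::geom_hline(yintercept = 1, colour = "black") +
    ggplot2::geom_point(position = ggplot2::position_jitter(width = 0.25),
                        size = 1.5, show.legend = FALSE) +
    ggplot2::scale_y_log10() +
    ggplot2::facet_wrap(~metabolite_id) +
    ggplot2::labs(
      x = NULL,
      y = sprintf("OR per %g%% reduction in primary-outcome risk",
                  100 * (1 - object$target_rr))) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}
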