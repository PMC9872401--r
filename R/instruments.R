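#' Select approximately independent genetic instruments by greedy LD clumping
#'
#' Keeps variants associated with the trait below the genome-wide significance
#' threshold, then clumps: survivors are visited in order of ascending p-value
#' (ties broken by variant id) and a variant is accepted unless it lies within
#' `window_kb` kilobases of an already-accepted variant on the same chromosome
#' *and* has r-squared at or above `r2_clump` with it — so within each
#' correlated group the variant with the lowest p-value is retained. Pairs
#' farther apart than the window are never clumped regardless of r-squared.
#'
#' @param assoc Validated summary-statistics tibble with `chrom`, `pos`,
#'   `pval` columns.
#' @param ld Squared-correlation matrix over (a superset of) the candidate
#'   variants. Variants absent from `ld` are treated as independent, with a
#'   warning.
#' @param p_threshold Strict significance cutoff; default `5e-8`.
#' @param r2_clump Variants at or above this r-squared are clumped; default 0.1.
#' @param window_kb Clumping half-window in kb around each accepted variant
#'   (i.e. a 1 Mb span at the default 500).
#' @return The retained rows of `assoc`, sorted by p-value, as a tibble.
#' @export
select_instruments <- function(assoc, ld = NULL, p_threshold = 5e-8,
                               r2_clump = 0.1, window_kb = 500) {
  assoc <- as_tibble(assoc)
  stopifnot(all(c("chrom", "pos", "pval") %in% names(assoc)))
  hits <- assoc[assoc$pval < p_threshold, , drop = FALSE]
  if (!nrow(hits)) return(hits)
  hits <- hits[order(hits$pval, hits$variant_id), , drop = FALSE]

  missing_ld <- if (is.null(ld)) hits$variant_id else
    setdiff(hits$variant_id, rownames(ld))
  if (length(missing_ld) && !is.null(ld)) {
    warn(glue::glue(
      "{length(missing_ld)} variant(s) absent from the LD matrix treated as independent"))
  }

  window_bp <- window_kb * 1000
  accepted <- integer()
  for (i in seq_len(nrow(hits))) {
    clumped <- FALSE
    for (j in accepted) {
      same_chrom <- hits$chrom[i] == hits$chrom[j]
      near <- same_chrom && abs(hits$pos[i] - hits$pos[j]) <= window_bp
      if (!near) next
      id_i <- hits$variant_id[i]; id_j <- hits$variant_id[j]
      r2 <- if (!is.null(ld) && id_i %in% rownames(ld) && id_j %in% colnames(ld))
        ld[id_i, id_j] else 0
      if (r2 >= r2_clump) { clumped <- TRUE; break }
    }
    if (!clumped) accepted <- c(accepted, i)
  }
  hits[accepted, , drop = FALSE]
}

#' Variance in the exposure explained by a set of instruments
#'
#' Uses the summary-statistic approximation: per variant,
#' `r2_j = F_j / (F_j + n - 2)` with `F_j = (beta_j / se_j)^2`, summed over
#' (approximately independent) instruments. An alternative allele-frequency
#' form `2 * eaf * (1 - eaf) * beta^2` is available via `method`.
#'
#' @param inst Instrument tibble with `beta` and `se` (and `eaf` for the
#'   frequency method).
#' @param n GWAS sample size; must exceed the instrument count plus one.
#' @param method `"f"` (default) or `"eaf"`.
#' @return Total R-squared in \[0, 1\].
#' @export
variance_explained <- function(inst, n, method = c("f", "eaf")) {
  method <- arg_match(method)
  k <- nrow(inst)
  if (n <= k + 1) {
    abort("sample size must exceed instrument count + 1",
          class = "metabomr_data_error")
  }
  if (method == "f") {
    f_j <- (inst$beta / inst$se)^2
    sum(f_j / (f_j + n - 2))
  } else {
    sum(2 * inst$eaf * (1 - inst$eaf) * inst$beta^2)
  }
}

#' Instrument-strength F-statistic
#'
#' `F = R2 * (n - k - 1) / (k * (1 - R2))`. Values below 10 indicate a weak
#' instrument at risk of weak-instrument bias.
#'
#' @param r2 Total variance explained, in \[0, 1).
#' @param n GWAS sample size.
#' @param k Number of instruments (at least 1).
#' @return A list with `f` and logical `weak` (`f < 10`).
#' @export
f_statistic <- function(r2, n, k) {
  if (r2 < 0 || r2 >= 1) {
    abort("R-squared must lie in [0, 1)", class = "metabomr_data_error")
  }
  if (k < 1 || n <= k + 1) {
    abort("need k >= 1 and n > k + 1", class = "metabomr_data_error")
  }
  f <- r2 * (n - k - 1) / (k * (1 - r2))
  list(f = f, weak = f < 10)
}

#' Summarise an instrument panel
#'
#' @param inst Instrument tibble (output of [select_instruments()]).
#' @param n GWAS sample size for the exposure.
#' @param trait_id Panel identifier.
#' @return One-row tibble: `trait_id`, `n_snps`, `r2_explained`, `f_statistic`,
#'   `weak`.
#' @export
instrument_stats <- function(inst, n, trait_id = attr(inst, "trait_id") %||% NA_character_) {
  k <- nrow(inst)
  if (k == 0) {
    return(tibble(trait_id = trait_id, n_snps = 0L, r2_explained = 0,
                  f_statistic = 0, weak = TRUE))
  }
  r2 <- variance_explained(inst, n)
  fs <- f_statistic(r2, n, k)
  tibble(trait_id = trait_id, n_snps = k, r2_explained = r2,
         f_statistic = fs$f, weak = fs$weak)
}

#' Panel-level quality-control filter
#'
#' Retains instrument panels explaining at least `min_r2` of the exposure
#' variance (default 0.5%) with at least `min_snps` instruments (default 3);
#' both bounds are inclusive, matching exclusion of panels with variance
#' explained *less than* 0.5% or *fewer than* 3 SNPs. Panels failing either
#' rule are reported with every reason that applies.
#'
#' @param panel_stats Tibble with one row per panel: `trait_id`, `n_snps`,
#'   `r2_explained` (e.g. bound rows of [instrument_stats()]).
#' @param min_r2 Minimum variance explained; default 0.005.
#' @param min_snps Minimum instrument count; default 3.
#' @return `panel_stats` with `status` (`"retained"`/`"excluded"`) and
#'   `reasons` (semicolon-joined, `NA` when retained) columns appended.
#' @export
qc_filter <- function(panel_stats, min_r2 = 0.005, min_snps = 3) {
  panel_stats <- as_tibble(panel_stats)
  reasons <- purrr::map2_chr(panel_stats$r2_explained, panel_stats$n_snps,
    function(r2, k) {
      why <- c(
        if (r2 < min_r2) glue::glue("variance < {min_r2 * 100}%"),
        if (k < min_snps) glue::glue("fewer than {min_snps} SNPs")
      )
      if (length(why)) paste(why, collapse = "; ") else NA_character_
    })
  panel_stats$status <- ifelse(is.na(reasons), "retained", "excluded")
  panel_stats$reasons <- reasons
  panel_stats
}
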