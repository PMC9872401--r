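COMPLEMENT <- c(A = "T", T = "A", C = "G", G = "C")

is_palindromic <- function(a1, a2) COMPLEMENT[a1] == a2

#' Find a proxy variant in linkage disequilibrium with a target
#'
#' When an instrument is absent from the outcome dataset, a nearby variant in
#' strong LD (r-squared above `r2_min`, 0.8 by default) can stand in for it.
#' Among candidates exceeding the threshold the one with maximal r-squared is
#' returned; exact ties are broken by the lexicographically smaller variant id
#' so the choice is deterministic.
#'
#' @param target Variant id to be proxied. Must be present in `ld`.
#' @param ld Squared-correlation matrix with variant-id dimnames.
#' @param candidates A summary-statistics tibble of variants available in the
#'   outcome dataset.
#' @param r2_min Strict lower bound on r-squared; default 0.8.
#' @return The chosen variant id, or `NA_character_` if no candidate exceeds
#'   `r2_min`.
#' @export
find_proxy <- function(target, ld, candidates, r2_min = 0.8) {
  if (!target %in% rownames(ld)) {
    abort(glue::glue("variant {target} not present in the LD matrix"),
          class = "metabomr_data_error")
  }
  ids <- setdiff(intersect(candidates$variant_id, colnames(ld)), target)
  if (!length(ids)) return(NA_character_)
  r2 <- ld[target, ids]
  ok <- which(r2 > r2_min)
  if (!length(ok)) return(NA_character_)
  best <- max(r2[ok])
  tied <- names(r2[ok])[r2[ok] == best]
  sort(tied)[1]
}

harmonize_one <- function(ea_x, oa_x, eaf_x, ea_y, oa_y, eaf_y,
                          palindromic_eaf_window) {
  # returns list(action, flip): flip means negate outcome beta / complement eaf
  if (is_palindromic(ea_x, oa_x)) {
    if (!setequal(c(ea_y, oa_y), c(ea_x, oa_x))) {
      return(list(action = "allele_mismatch", flip = NA))
    }
    if (is.na(eaf_x) || abs(eaf_x - 0.5) < palindromic_eaf_window) {
      return(list(action = "dropped_palindromic", flip = NA))
    }
    # orient outcome record to the exposure effect allele by id first
    flip <- ea_y != ea_x
    eaf_y_oriented <- if (is.na(eaf_y)) NA_real_ else if (flip) 1 - eaf_y else eaf_y
    if (!is.na(eaf_y_oriented) &&
        (eaf_x - 0.5) * (eaf_y_oriented - 0.5) < 0) {
      # frequencies disagree: the two studies report opposite strands
      flip <- !flip
    }
    return(list(action = if (flip) "flipped" else "aligned", flip = flip))
  }
  pair_y <- c(ea_y, oa_y)
  pair_yc <- unname(COMPLEMENT[pair_y])
  if (identical(pair_y, c(ea_x, oa_x)) || identical(pair_yc, c(ea_x, oa_x))) {
    return(list(action = "aligned", flip = FALSE))
  }
  if (identical(pair_y, c(oa_x, ea_x)) || identical(pair_yc, c(oa_x, ea_x))) {
    return(list(action = "flipped", flip = TRUE))
  }
  list(action = "allele_mismatch", flip = NA)
}

#' Harmonize exposure and outcome summary statistics
#'
#' Joins exposure and outcome association tables on variant id and aligns the
#' outcome effect to the exposure effect allele. Allele swaps flip the sign of
#' the outcome beta (and complement its frequency); strand flips (e.g. A/G
#' reported as T/C) are resolved by complementing before comparison.
#' Palindromic variants (A/T or C/G) are dropped when the exposure
#' effect-allele frequency is missing or lies within `palindromic_eaf_window`
#' of 0.5, and otherwise oriented by allele frequency. Irreconcilable allele
#' pairs are dropped with reason `"allele mismatch"`.
#'
#' When an LD matrix is supplied, instruments absent from the outcome table
#' are replaced by a proxy variant (r-squared above `r2_proxy`) present in the
#' outcome table, recorded with action `"proxy_substituted"`. The proxy's own
#' exposure association is taken from `proxy_source` — typically the full
#' exposure GWAS, since a variant tagging an instrument will have been clumped
#' out of the instrument panel itself; variants already serving as instruments
#' are never reused as proxies.
#'
#' @param exposure,outcome Validated summary-statistics tibbles.
#' @param palindromic_eaf_window Half-width of the frequency window around 0.5
#'   inside which palindromic variants are considered unorientable; default
#'   0.08 (drop when eaf is in (0.42, 0.58)).
#' @param ld Optional squared-correlation matrix enabling proxy substitution.
#' @param r2_proxy Strict r-squared threshold for proxies; default 0.8.
#' @param proxy_source Association table supplying exposure statistics for
#'   proxy variants; defaults to `exposure`.
#' @return A tibble of harmonized instruments with columns `variant_id`,
#'   `beta_exposure`, `se_exposure`, `beta_outcome`, `se_outcome`,
#'   `eaf_exposure` and `action_taken`; dropped variants are reported in the
#'   `"dropped"` attribute with reasons.
#' @examples
#' exp <- tibble::tibble(variant_id = "rs1", effect_allele = "A",
#'   other_allele = "G", eaf = 0.3, beta = 0.1, se = 0.01, pval = 1e-10)
#' out <- tibble::tibble(variant_id = "rs1", effect_allele = "G",
#'   other_allele = "A", eaf = 0.7, beta = 0.05, se = 0.02, pval = 0.01)
#' harmonize(exp, out) # outcome beta becomes -0.05
#' @export
harmonize <- function(exposure, outcome, palindromic_eaf_window = 0.08,
                      ld = NULL, r2_proxy = 0.8, proxy_source = exposure) {
  exposure <- as_tibble(exposure)
  outcome <- as_tibble(outcome)
  proxy_source <- as_tibble(proxy_source)
  if (!"eaf" %in% names(exposure)) exposure$eaf <- NA_real_
  if (!"eaf" %in% names(outcome)) outcome$eaf <- NA_real_
  if (!"eaf" %in% names(proxy_source)) proxy_source$eaf <- NA_real_

  out_idx <- setNames(seq_len(nrow(outcome)), outcome$variant_id)
  dropped <- tibble(variant_id = character(), reason = character())
  rows <- vector("list", nrow(exposure))
  used_proxies <- character()

  for (i in seq_len(nrow(exposure))) {
    ex <- exposure[i, ]
    id <- ex$variant_id
    action_prefix <- NULL
    if (!id %in% names(out_idx)) {
      proxy <- NA_character_
      if (!is.null(ld) && id %in% rownames(ld)) {
        cand <- outcome[outcome$variant_id %in% proxy_source$variant_id &
                          !outcome$variant_id %in%
                            c(used_proxies, exposure$variant_id), ,
                        drop = FALSE]
        proxy <- find_proxy(id, ld, cand, r2_min = r2_proxy)
      }
      if (is.na(proxy)) {
        dropped <- bind_rows(dropped, tibble(variant_id = id,
                                             reason = "absent from outcome"))
        next
      }
      used_proxies <- c(used_proxies, proxy)
      ex <- proxy_source[proxy_source$variant_id == proxy, ][1, ]
      id <- proxy
      action_prefix <- "proxy_substituted"
    }
    oc <- outcome[out_idx[[id]], ]
    h <- harmonize_one(ex$effect_allele, ex$other_allele, ex$eaf,
                       oc$effect_allele, oc$other_allele, oc$eaf,
                       palindromic_eaf_window)
    if (h$action == "allele_mismatch") {
      dropped <- bind_rows(dropped, tibble(variant_id = id,
                                           reason = "allele mismatch"))
      next
    }
    if (h$action == "dropped_palindromic") {
      dropped <- bind_rows(dropped, tibble(variant_id = id,
                                           reason = "palindromic near 0.5"))
      next
    }
    rows[[i]] <- tibble(
      variant_id = id,
      beta_exposure = ex$beta,
      se_exposure = ex$se,
      beta_outcome = if (h$flip) -oc$beta else oc$beta,
      se_outcome = oc$se,
      eaf_exposure = ex$eaf,
      action_taken = action_prefix %||% h$action
    )
  }
  res <- bind_rows(rows)
  if (!nrow(res)) {
    res <- tibble(variant_id = character(), beta_exposure = double(),
                  se_exposure = double(), beta_outcome = double(),
                  se_outcome = double(), eaf_exposure = double(),
                  action_taken = character())
  }
  attr(res, "dropped") <- dropped
  res
}
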