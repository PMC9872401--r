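# Independent oracle implementations and fixture builders used across the
# suite. These are deliberately written from the definitions, not by calling
# package internals, so they can catch implementation errors.

# minimal well-formed association row(s)
assoc_fixture <- function(variant_id = "rs1", chrom = "1", pos = 1000,
                          effect_allele = "A", other_allele = "G",
                          eaf = 0.3, beta = 0.1, se = 0.01, pval = 1e-10,
                          n = 10000) {
  tibble::tibble(variant_id = variant_id, chrom = chrom, pos = pos,
                 effect_allele = effect_allele, other_allele = other_allele,
                 eaf = eaf, beta = beta, se = se, pval = pval, n = n)
}

# harmonized-instrument tibble built directly (already aligned)
harm_fixture <- function(bx, by, sx = rep(0.01, length(bx)),
                         sy = rep(0.01, length(bx))) {
  tibble::tibble(
    variant_id = sprintf("rs%03d", seq_along(bx)),
    beta_exposure = bx, se_exposure = sx,
    beta_outcome = by, se_outcome = sy,
    eaf_exposure = 0.3, action_taken = "aligned"
  )
}

# bypass harmonization for bulk simulation studies: requires a truth with
# swap_fraction = 0 so exposure and outcome rows are already aligned
harm_direct <- function(sim) {
  tibble::tibble(
    variant_id = sim$exposure$variant_id,
    beta_exposure = sim$exposure$beta, se_exposure = sim$exposure$se,
    beta_outcome = sim$outcome$beta, se_outcome = sim$outcome$se,
    eaf_exposure = sim$exposure$eaf, action_taken = "aligned"
  )
}

# ten-entry phenotype catalog with known exclusions: 499-case, sex-specific
# and redundant entries alongside clean ones
catalog_fixture <- function() {
  tibble::tibble(
    phecode = sprintf("%03d", 1:10),
    label = sprintf("trait %d", 1:10),
    icd_chapter = rep(c("circulatory system", "mental disorders"), 5),
    n_cases = c(499L, 500L, 5000L, 100L, 499L, 2000L, 3000L, 4000L, 5000L, 6000L),
    n_controls = rep(100000L, 10),
    sex_specific = c(FALSE, FALSE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE,
                     FALSE, FALSE),
    redundant_of = c(NA, NA, NA, NA, NA, "002", NA, NA, NA, NA)
  )
}

# origin-constrained weighted least squares slope (IVW oracle)
oracle_ivw_wls <- function(bx, by, sy) {
  w <- 1 / sy^2
  sum(w * bx * by) / sum(w * bx^2)
}

# interpolated weighted percentile at 0.5, coded from the definition with an
# explicit interpolation loop
oracle_weighted_median <- function(b, w) {
  o <- order(b)
  b <- b[o]; w <- w[o] / sum(w)
  s <- numeric(length(w))
  acc <- 0
  for (j in seq_along(w)) {
    s[j] <- acc + w[j] / 2
    acc <- acc + w[j]
  }
  if (0.5 <= s[1]) return(b[1])
  if (0.5 >= s[length(s)]) return(b[length(b)])
  j <- max(which(s < 0.5))
  b[j] + (0.5 - s[j]) / (s[j + 1] - s[j]) * (b[j + 1] - b[j])
}

# weighted least squares with intercept via the normal equations (Egger oracle)
oracle_egger_wls <- function(bx, by, sy) {
  flip <- ifelse(bx < 0, -1, 1)
  bx <- bx * flip; by <- by * flip
  X <- cbind(1, bx)
  W <- diag(1 / sy^2)
  unname(solve(t(X) %*% W %*% X, t(X) %*% W %*% by)[, 1])
}

# grid-search maximizer of the RAPS profile log-likelihood (l2 loss, no
# overdispersion): l(b) = -0.5 * sum((by - b*bx)^2 / (sy^2 + b^2*sx^2))
oracle_raps_grid <- function(bx, by, sx, sy, lo = -3, hi = 3) {
  ll <- function(b) -0.5 * sum((by - b * bx)^2 / (sy^2 + b^2 * sx^2))
  grid <- seq(lo, hi, length.out = 4001)
  b0 <- grid[which.max(vapply(grid, ll, numeric(1)))]
  stats::optimize(ll, c(b0 - 0.01, b0 + 0.01), maximum = TRUE,
                  tol = 1e-10)$maximum
}

# greedy clumping oracle following the stated algorithm literally
oracle_clump <- function(assoc, ld, p_threshold, r2_clump, window_kb) {
  hits <- assoc[assoc$pval < p_threshold, , drop = FALSE]
  hits <- hits[order(hits$pval, hits$variant_id), , drop = FALSE]
  kept <- character()
  for (i in seq_len(nrow(hits))) {
    ok <- TRUE
    for (id in kept) {
      j <- which(hits$variant_id == id)
      if (hits$chrom[i] != hits$chrom[j]) next
      if (abs(hits$pos[i] - hits$pos[j]) > window_kb * 1000) next
      r2 <- if (hits$variant_id[i] %in% rownames(ld) && id %in% colnames(ld))
        ld[hits$variant_id[i], id] else 0
      if (r2 >= r2_clump) { ok <- FALSE; break }
    }
    if (ok) kept <- c(kept, hits$variant_id[i])
  }
  kept
}

# hand-written allele truth table for harmonization of non-palindromic pairs:
# returns "aligned", "flipped" or "mismatch"
oracle_allele_action <- function(ea_x, oa_x, ea_y, oa_y) {
  comp <- c(A = "T", T = "A", C = "G", G = "C")
  same <- function(p, q) identical(p, q)
  x <- c(ea_x, oa_x)
  for (y in list(c(ea_y, oa_y), unname(comp[c(ea_y, oa_y)]))) {
    if (same(y, x)) return("aligned")
    if (same(y, rev(x))) return("flipped")
  }
  "mismatch"
}
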