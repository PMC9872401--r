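# run code with a private RNG stream, restoring the caller's state
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

mr_est_row <- function(method, beta, se, n_snps, pval = NULL,
                       q_stat = NA_real_, q_df = NA_real_, q_pval = NA_real_,
                       egger_intercept = NA_real_,
                       egger_intercept_pval = NA_real_,
                       overdispersion_tau2 = NA_real_) {
  if (is.null(pval)) {
    pval <- if (is.na(se) || is.na(beta)) NA_real_
      else if (se == 0) as.numeric(beta == 0)
      else 2 * pnorm(-abs(beta / se))
  }
  tibble(
    method = method, beta = beta, se = se,
    ci_low = beta - Z95 * se, ci_high = beta + Z95 * se,
    pval = pval, n_snps = as.integer(n_snps),
    q_stat = q_stat, q_df = q_df, q_pval = q_pval,
    egger_intercept = egger_intercept,
    egger_intercept_pval = egger_intercept_pval,
    overdispersion_tau2 = overdispersion_tau2
  )
}

#' Per-instrument Wald ratio estimates
#'
#' The instrument-level causal estimate is the outcome effect divided by the
#' exposure effect. The default first-order standard error is
#' `se_outcome / |beta_exposure|`; the second-order (delta-method) option adds
#' the exposure-uncertainty term
#' `beta_outcome^2 * se_exposure^2 / beta_exposure^4` under the square root.
#' Instruments with a zero exposure effect are dropped with a warning.
#'
#' @param instr Harmonized-instrument tibble from [harmonize()].
#' @param se_method `"first"` (default) or `"second"` order.
#' @return Tibble with `variant_id`, `beta_ratio`, `se_ratio` and inverse-
#'   variance `weight`.
#' @export
wald_ratios <- function(instr, se_method = c("first", "second")) {
  se_method <- arg_match(se_method)
  drop <- instr$beta_exposure == 0
  if (any(drop)) {
    warn(glue::glue("{sum(drop)} instrument(s) with zero exposure effect dropped"))
    instr <- instr[!drop, , drop = FALSE]
  }
  bx <- instr$beta_exposure; by <- instr$beta_outcome
  sx <- instr$se_exposure; sy <- instr$se_outcome
  se <- if (se_method == "first") sy / abs(bx) else
    sqrt(sy^2 / bx^2 + by^2 * sx^2 / bx^4)
  tibble(variant_id = instr$variant_id, beta_ratio = by / bx,
         se_ratio = se, weight = se^-2)
}

#' Cochran's Q heterogeneity statistic
#'
#' `Q = sum(w_j * (beta_j - beta_hat)^2)` over instruments, on `J - 1` degrees
#' of freedom, with the p-value from the upper tail of the chi-square
#' distribution.
#'
#' @param ratios Wald-ratio tibble from [wald_ratios()].
#' @param beta_hat Pooled estimate at which to evaluate the quadratic form
#'   (the inverse-variance-weighted mean minimises it).
#' @return A list with `q`, `df` and `pval`.
#' @export
cochran_q <- function(ratios, beta_hat) {
  if (nrow(ratios) < 2) {
    abort("Cochran's Q needs at least 2 instruments",
          class = "metabomr_data_error")
  }
  q <- sum(ratios$weight * (ratios$beta_ratio - beta_hat)^2)
  df <- nrow(ratios) - 1
  list(q = q, df = df, pval = pchisq(q, df, lower.tail = FALSE))
}

#' Inverse-variance-weighted causal estimate
#'
#' The IVW estimate is the weighted mean of the Wald ratios with weights
#' `1 / se_j^2`. The fixed-effect standard error is `sum(w)^(-1/2)`; the
#' (multiplicative) random-effects standard error inflates it by
#' `max(1, sqrt(Q / (J - 1)))`. With `model = "auto"` the random-effects model
#' is used when Cochran's Q gives p < 0.05 — i.e. when heterogeneity exists —
#' and the fixed-effect model otherwise.
#'
#' @param ratios Wald-ratio tibble from [wald_ratios()]; at least 2 rows.
#' @param model `"auto"` (default), `"fixed"` or `"random"`.
#' @return One-row estimate tibble (method `"IVW_fixed"` or `"IVW_random"`)
#'   with heterogeneity columns filled in.
#' @export
mr_ivw <- function(ratios, model = c("auto", "fixed", "random")) {
  model <- arg_match(model)
  if (nrow(ratios) < 2) {
    abort("IVW needs at least 2 instruments", class = "metabomr_data_error")
  }
  w <- ratios$weight
  beta <- sum(w * ratios$beta_ratio) / sum(w)
  se_fixed <- sum(w)^-0.5
  het <- cochran_q(ratios, beta)
  use_random <- switch(model, fixed = FALSE, random = TRUE,
                       auto = het$pval < 0.05)
  se <- if (use_random) se_fixed * max(1, sqrt(het$q / het$df)) else se_fixed
  mr_est_row(if (use_random) "IVW_random" else "IVW_fixed",
             beta, se, nrow(ratios),
             q_stat = het$q, q_df = het$df, q_pval = het$pval)
}

weighted_median_point <- function(b, w) {
  ord <- order(b)
  b <- b[ord]; w <- w[ord] / sum(w)
  s <- cumsum(w) - w / 2
  if (0.5 <= s[1]) return(b[1])
  if (0.5 >= s[length(s)]) return(b[length(b)])
  approx(s, b, xout = 0.5, ties = "ordered")$y
}

#' Weighted-median causal estimate
#'
#' The estimate is the interpolated weighted 50th percentile of the ordered
#' Wald ratios and remains consistent when up to half of the total weight lies
#' on invalid instruments. The standard error comes from a parametric
#' bootstrap: each ratio is resampled from `Normal(beta_j, se_j)`, the weighted
#' median recomputed, and the standard deviation over replicates taken; the
#' bootstrap is seeded for reproducibility and does not disturb the caller's
#' RNG state.
#'
#' @param ratios Wald-ratio tibble; at least 3 rows.
#' @param n_boot Bootstrap replicates; default 1000.
#' @param seed Seed for the bootstrap; default 1.
#' @return One-row estimate tibble, method `"weighted_median"`.
#' @export
mr_weighted_median <- function(ratios, n_boot = 1000, seed = 1) {
  if (nrow(ratios) < 3) {
    abort("weighted median needs at least 3 instruments",
          class = "metabomr_data_error")
  }
  b <- ratios$beta_ratio; w <- ratios$weight; s <- ratios$se_ratio
  est <- weighted_median_point(b, w)
  boots <- with_local_seed(seed, {
    vapply(seq_len(n_boot), function(i) {
      weighted_median_point(rnorm(length(b), b, s), w)
    }, numeric(1))
  })
  mr_est_row("weighted_median", est, sd(boots), nrow(ratios))
}

#' MR-Egger regression
#'
#' Weighted least squares of the outcome effects on the exposure effects with
#' an unconstrained intercept and weights `1 / se_outcome^2`, after orienting
#' every instrument so its exposure effect is positive. The slope is the
#' causal estimate; a nonzero intercept is evidence of directional horizontal
#' pleiotropy, with two-sided p < 0.05 taken as suggestive. The residual
#' standard deviation is floored at 1 when scaling coefficient standard
#' errors, so precision never exceeds the fixed-effect analysis.
#'
#' @param instr Harmonized-instrument tibble; at least 3 instruments.
#' @param pval_dist `"normal"` (default) or `"t"` for coefficient p-values.
#' @return One-row estimate tibble, method `"MR_Egger"`, carrying
#'   `egger_intercept` and `egger_intercept_pval`.
#' @export
mr_egger <- function(instr, pval_dist = c("normal", "t")) {
  pval_dist <- arg_match(pval_dist)
  if (nrow(instr) < 3) {
    abort("MR-Egger needs at least 3 instruments",
          class = "metabomr_data_error")
  }
  flip <- sign(instr$beta_exposure)
  flip[flip == 0] <- 1
  bx <- instr$beta_exposure * flip
  by <- instr$beta_outcome * flip
  if (length(unique(bx)) < 2) {
    abort("singular design: all exposure effects equal",
          class = "metabomr_data_error")
  }
  fit <- lm(by ~ bx, weights = 1 / instr$se_outcome^2)
  sm <- summary(fit)
  co <- sm$coefficients
  scale <- min(1, sm$sigma)     # floor residual SD at 1
  if (scale == 0) scale <- 1    # perfect fit: keep the zero SEs
  se_slope <- co["bx", "Std. Error"] / scale
  se_int <- co["(Intercept)", "Std. Error"] / scale
  slope <- unname(coef(fit)["bx"])
  intercept <- unname(coef(fit)["(Intercept)"])
  pfun <- if (pval_dist == "normal") {
    function(est, se) if (se == 0) as.numeric(est == 0) else 2 * pnorm(-abs(est / se))
  } else {
    df <- fit$df.residual
    function(est, se) if (se == 0) as.numeric(est == 0) else
      2 * stats::pt(-abs(est / se), df)
  }
  mr_est_row("MR_Egger", slope, se_slope, nrow(instr),
             pval = pfun(slope, se_slope),
             egger_intercept = intercept,
             egger_intercept_pval = pfun(intercept, se_int))
}

raps_rho_prime <- function(t, loss, c_huber) {
  if (loss == "l2") t else pmin(pmax(t, -c_huber), c_huber)
}

#' Robust adjusted profile score (RAPS) causal estimate
#'
#' Solves the profile-score estimating equation
#' `sum_j rho'(t_j) * dt_j/dbeta = 0` with standardised residuals
#' `t_j = (beta_Yj - beta * beta_Xj) / sqrt(se_Yj^2 + beta^2 * se_Xj^2 + tau2)`,
#' which accounts for exposure measurement error and so tolerates weak
#' instruments. `rho` is either the squared-error loss or the Huber loss
#' (constant 1.345), the latter down-weighting outlying (pleiotropic)
#' instruments. With `overdispersion = TRUE` a systematic-pleiotropy variance
#' `tau2 >= 0` is estimated jointly from the calibration equation
#' `sum_j (rho'(t_j) * t_j - delta) / s_j^2 = 0`, where `delta = E[rho'(Z) Z]`
#' for standard-normal `Z`. Standard errors come from the empirical sandwich
#' of the per-instrument scores. The solver starts from the IVW estimate and
#' is deterministic given the inputs.
#'
#' @param instr Harmonized-instrument tibble; at least 3 instruments.
#' @param loss `"huber"` (default) or `"l2"`.
#' @param overdispersion Estimate `tau2` jointly; default `TRUE`.
#' @param c_huber Huber constant; default 1.345.
#' @param max_iter,tol Convergence controls for the alternating solver.
#' @return One-row estimate tibble, method `"MR_RAPS"`, with
#'   `overdispersion_tau2`.
#' @export
mr_raps <- function(instr, loss = c("huber", "l2"), overdispersion = TRUE,
                    c_huber = 1.345, max_iter = 200, tol = 1e-10) {
  loss <- arg_match(loss)
  if (nrow(instr) < 3) {
    abort("MR-RAPS needs at least 3 instruments",
          class = "metabomr_data_error")
  }
  bx <- instr$beta_exposure; by <- instr$beta_outcome
  sx <- instr$se_exposure; sy <- instr$se_outcome
  delta <- if (loss == "l2") 1 else 2 * pnorm(c_huber) - 1

  score_parts <- function(beta, tau2) {
    s2 <- sy^2 + beta^2 * sx^2 + tau2
    s <- sqrt(s2)
    t <- (by - beta * bx) / s
    dtdb <- -(bx / s + t * beta * sx^2 / s2)
    rp <- raps_rho_prime(t, loss, c_huber)
    list(beta_j = rp * dtdb, tau_j = (rp * t - delta) / s2)
  }
  score_beta <- function(beta, tau2) sum(score_parts(beta, tau2)$beta_j)
  score_tau <- function(tau2, beta) sum(score_parts(beta, tau2)$tau_j)

  start <- mr_ivw(wald_ratios(instr), model = "fixed")$beta
  solve_beta <- function(tau2, beta0) {
    span <- max(1, abs(beta0))
    tryCatch(
      uniroot(score_beta, c(beta0 - span, beta0 + span), tau2 = tau2,
              extendInt = "yes", tol = 1e-12, maxiter = 1000)$root,
      error = function(e) abort(
        glue::glue("MR-RAPS failed to converge (last beta {signif(beta0, 6)})"),
        class = "metabomr_convergence_error"))
  }
  solve_tau <- function(beta) {
    if (score_tau(0, beta) <= 0) return(0)
    upper <- max(sy^2)
    while (score_tau(upper, beta) > 0 && upper < 1e6) upper <- upper * 4
    uniroot(score_tau, c(0, upper), beta = beta, tol = 1e-14)$root
  }

  beta <- start; tau2 <- 0
  for (iter in seq_len(max_iter)) {
    beta_new <- solve_beta(tau2, beta)
    tau2_new <- if (overdispersion) solve_tau(beta_new) else 0
    done <- abs(beta_new - beta) < tol && abs(tau2_new - tau2) < tol
    beta <- beta_new; tau2 <- tau2_new
    if (done) break
  }

  # empirical sandwich variance from the per-instrument scores
  theta <- if (overdispersion) c(beta, tau2) else beta
  psi_mat <- function(th) {
    p <- score_parts(th[1], if (overdispersion) max(th[2], 0) else 0)
    if (overdispersion) cbind(p$beta_j, p$tau_j) else cbind(p$beta_j)
  }
  eps <- pmax(1e-6, abs(theta) * 1e-6)
  d <- length(theta)
  A <- matrix(0, d, d)
  for (k in seq_len(d)) {
    up <- theta; up[k] <- up[k] + eps[k]
    dn <- theta; dn[k] <- dn[k] - eps[k]
    if (overdispersion && k == 2 && dn[2] < 0) dn[2] <- 0
    A[, k] <- (colSums(psi_mat(up)) - colSums(psi_mat(dn))) / (up[k] - dn[k])
  }
  psi <- psi_mat(theta)
  B <- crossprod(psi)
  V <- tryCatch(solve(A) %*% B %*% t(solve(A)), error = function(e) {
    matrix(NA_real_, d, d)
  })
  se <- sqrt(abs(V[1, 1]))

  mr_est_row("MR_RAPS", beta, se, nrow(instr),
             overdispersion_tau2 = tau2)
}

#' Convert a log-scale estimate to an odds ratio with 95% CI
#'
#' @param est One-row estimate tibble with `beta` and `se` on the log-odds
#'   scale (any estimator output).
#' @return Tibble with `or`, `or_ci_low`, `or_ci_high`.
#' @export
mr_to_or <- function(est) {
  tibble(or = exp(est$beta),
         or_ci_low = exp(est$beta - Z95 * est$se),
         or_ci_high = exp(est$beta + Z95 * est$se))
}

#' Fit the full battery of two-sample MR estimators
#'
#' Runs IVW (with automatic fixed/random model choice via Cochran's Q), the
#' weighted median, MR-RAPS and MR-Egger on one set of harmonized instruments
#' and collects the estimates in a single object with [tidy()], [glance()] and
#' [autoplot()] methods.
#'
#' @param instr Harmonized-instrument tibble from [harmonize()].
#' @param ivw_model Passed to [mr_ivw()].
#' @param n_boot,seed Weighted-median bootstrap controls.
#' @param raps_loss,raps_overdispersion Passed to [mr_raps()].
#' @param exposure,outcome Optional trait labels stored on the fit.
#' @return An object of class `mr_fit`.
#' @examples
#' sim <- simulate_gwas_pair(simulation_truth(true_beta = 0.2, seed = 7))
#' fit <- mr_fit(harmonize(sim$exposure, sim$outcome))
#' tidy(fit)
#' @export
mr_fit <- function(instr, ivw_model = "auto", n_boot = 1000, seed = 1,
                   raps_loss = "huber", raps_overdispersion = TRUE,
                   exposure = NA_character_, outcome = NA_character_) {
  ratios <- wald_ratios(instr)
  est <- bind_rows(
    mr_ivw(ratios, model = ivw_model),
    mr_weighted_median(ratios, n_boot = n_boot, seed = seed),
    mr_raps(instr, loss = raps_loss, overdispersion = raps_overdispersion),
    mr_egger(instr)
  )
  structure(
    list(estimates = est, ratios = ratios, data = instr,
         exposure = exposure, outcome = outcome),
    class = "mr_fit"
  )
}

#' @export
print.mr_fit <- function(x, ...) {
  cat("Two-sample MR fit:",
      if (!is.na(x$exposure)) paste(x$exposure, "->", x$outcome) else "",
      "\n")
  cat(nrow(x$data), "harmonized instruments\n\n")
  print(as.data.frame(x$estimates[, c("method", "beta", "se", "pval")]),
        row.names = FALSE)
  invisible(x)
}

#' @rdname mr_fit
#' @param x An `mr_fit` object.
#' @param ... Unused.
#' @export
tidy.mr_fit <- function(x, ...) x$estimates

#' @rdname mr_fit
#' @export
glance.mr_fit <- function(x, ...) {
  ivw <- x$estimates[grepl("^IVW", x$estimates$method), ][1, ]
  egger <- x$estimates[x$estimates$method == "MR_Egger", ][1, ]
  tibble(
    n_snps = ivw$n_snps, ivw_model = ivw$method,
    beta_ivw = ivw$beta, se_ivw = ivw$se, pval_ivw = ivw$pval,
    q_stat = ivw$q_stat, q_pval = ivw$q_pval,
    egger_intercept = egger$egger_intercept,
    egger_intercept_pval = egger$egger_intercept_pval
  )
}
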