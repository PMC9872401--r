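test_that("Wald ratios follow the definition and first-order SE", {
  h <- harm_fixture(bx = c(0.5, -0.5), by = c(0.25, 0.25),
                    sy = c(0.05, 0.05))
  r <- wald_ratios(h)
  expect_equal(r$beta_ratio, c(0.5, -0.5))
  expect_equal(r$se_ratio, c(0.1, 0.1))   # se uses |beta_exposure|
  expect_equal(r$weight, 1 / r$se_ratio^2)

  hz <- harm_fixture(bx = c(0.5, 0), by = c(0.25, 0.1))
  expect_warning(rz <- wald_ratios(hz), "zero exposure")
  expect_equal(nrow(rz), 1)
})

test_that("second-order ratio SE matches a Monte-Carlo oracle", {
  bx <- 0.5; sx <- 0.05; by <- 0.25; sy <- 0.05
  h <- harm_fixture(bx, by, sx, sy)
  se2 <- wald_ratios(h, se_method = "second")$se_ratio
  emp <- withr::with_seed(42, {
    num <- rnorm(1e6, by, sy)
    den <- rnorm(1e6, bx, sx)
    sd(num / den)
  })
  expect_equal(se2, emp, tolerance = 0.05)
  expect_gt(se2, wald_ratios(h)$se_ratio)  # exposure noise adds uncertainty
})

test_that("IVW reproduces the hand-computed weighted mean, SE and Q", {
  r <- tibble::tibble(variant_id = c("a", "b"), beta_ratio = c(0.4, 0.6),
                      se_ratio = c(0.1, 0.2), weight = c(100, 25))
  est <- mr_ivw(r, model = "fixed")
  expect_equal(est$beta, (0.4 * 100 + 0.6 * 25) / 125)
  expect_equal(est$se, 125^-0.5)
  expect_equal(est$q_stat, 100 * (0.4 - 0.44)^2 + 25 * (0.6 - 0.44)^2)
  expect_equal(est$q_df, 1)

  # identical ratios: zero heterogeneity, auto stays fixed
  rid <- tibble::tibble(variant_id = c("a", "b", "c"),
                        beta_ratio = rep(0.5, 3),
                        se_ratio = c(0.1, 0.1, 0.2),
                        weight = c(100, 100, 25))
  est0 <- mr_ivw(rid, model = "auto")
  expect_equal(est0$beta, 0.5)
  expect_equal(est0$q_stat, 0)
  expect_equal(est0$method, "IVW_fixed")
  expect_equal(est0$ci_high - est0$beta, est0$beta - est0$ci_low)
  expect_error(mr_ivw(r[1, ]), class = "metabomr_data_error")
})

test_that("IVW equals origin-constrained WLS on random instances", {
  for (seed in 1:10) {
    h <- withr::with_seed(seed, {
      k <- sample(5:30, 1)
      harm_fixture(bx = rnorm(k, 0.1, 0.03), by = rnorm(k, 0.02, 0.02),
                   sx = runif(k, 0.005, 0.02), sy = runif(k, 0.005, 0.03))
    })
    r <- wald_ratios(h)
    expect_equal(mr_ivw(r, model = "fixed")$beta,
                 oracle_ivw_wls(h$beta_exposure, h$beta_outcome,
                                h$se_outcome))
  }
})

test_that("Cochran's Q is a homogeneous quadratic form minimised at IVW", {
  r <- tibble::tibble(variant_id = letters[1:4],
                      beta_ratio = c(0.1, 0.3, 0.2, 0.5),
                      se_ratio = c(0.1, 0.2, 0.15, 0.3),
                      weight = c(100, 25, 1 / 0.15^2, 1 / 0.09))
  bh <- mr_ivw(r, model = "fixed")$beta
  q <- cochran_q(r, bh)
  # scaling all weights by c scales Q by c
  rs <- r; rs$weight <- r$weight * 3
  expect_equal(cochran_q(rs, bh)$q, 3 * q$q)
  # minimum over beta is attained at the IVW estimate
  for (b in bh + c(-0.05, -0.01, 0.01, 0.05)) {
    expect_gt(cochran_q(r, b)$q, q$q)
  }
  # identical ratios: Q = 0, p = 1
  rid <- tibble::tibble(variant_id = c("a", "b"), beta_ratio = c(1, 1),
                        se_ratio = c(0.1, 0.1), weight = c(100, 100))
  expect_equal(cochran_q(rid, 1)$q, 0)
  expect_equal(cochran_q(rid, 1)$pval, 1)
})

test_that("the weighted median reduces to the median and matches the oracle", {
  r3 <- tibble::tibble(variant_id = letters[1:3],
                       beta_ratio = c(0.1, 0.5, 0.9),
                       se_ratio = rep(0.1, 3), weight = rep(100, 3))
  expect_equal(mr_weighted_median(r3, n_boot = 50)$beta, 0.5)

  rc <- r3; rc$beta_ratio <- rep(0.3, 3); rc$weight <- c(1, 10, 100)
  expect_equal(mr_weighted_median(rc, n_boot = 50)$beta, 0.3)

  for (seed in 1:10) {
    r <- withr::with_seed(seed, {
      k <- sample(4:20, 1)
      se <- runif(k, 0.05, 0.3)
      tibble::tibble(variant_id = sprintf("v%d", 1:k),
                     beta_ratio = rnorm(k, 0.2, 0.3),
                     se_ratio = se, weight = 1 / se^2)
    })
    expect_equal(mr_weighted_median(r, n_boot = 10)$beta,
                 oracle_weighted_median(r$beta_ratio, r$weight))
  }
  expect_error(mr_weighted_median(r3[1:2, ]), class = "metabomr_data_error")
})

test_that("the weighted-median bootstrap is seeded and RNG-clean", {
  r <- tibble::tibble(variant_id = letters[1:5],
                      beta_ratio = c(0.1, 0.2, 0.3, 0.4, 0.5),
                      se_ratio = rep(0.1, 5), weight = rep(100, 5))
  before <- withr::with_seed(99, runif(1))
  withr::with_seed(99, {
    runif(0)
    e1 <- mr_weighted_median(r, n_boot = 100, seed = 5)
    after <- runif(1)
  })
  e2 <- mr_weighted_median(r, n_boot = 100, seed = 5)
  expect_equal(e1$se, e2$se)      # same seed, same bootstrap SE
  expect_equal(before, after)     # caller's RNG stream untouched
})

test_that("MR-Egger equals weighted least squares with intercept", {
  bx <- c(0.1, 0.2, 0.3, 0.4, 0.5)
  h_exact <- harm_fixture(bx, by = 0.1 + 0.3 * bx, sy = rep(0.05, 5))
  e <- mr_egger(h_exact)
  expect_equal(e$beta, 0.3)
  expect_equal(e$egger_intercept, 0.1)

  h_null <- harm_fixture(bx, by = rep(0, 5))
  e0 <- mr_egger(h_null)
  expect_equal(e0$beta, 0)
  expect_equal(e0$egger_intercept, 0)

  for (seed in 1:5) {
    h <- withr::with_seed(seed, harm_fixture(
      bx = rnorm(5, 0.3, 0.2), by = rnorm(5, 0.05, 0.05),
      sy = runif(5, 0.01, 0.1)))
    got <- mr_egger(h)
    want <- oracle_egger_wls(h$beta_exposure, h$beta_outcome, h$se_outcome)
    expect_equal(got$egger_intercept, want[1])
    expect_equal(got$beta, want[2])
  }
  expect_error(mr_egger(h_exact[1:2, ]), class = "metabomr_data_error")
  expect_error(mr_egger(harm_fixture(rep(0.3, 4), rnorm(4))),
               class = "metabomr_data_error")
})

test_that("MR-RAPS recovers exact proportional data and the l2 profile maximum", {
  bx <- c(0.1, 0.25, 0.3, 0.45, 0.5)
  h <- harm_fixture(bx, by = 0.4 * bx, sx = rep(0.01, 5), sy = rep(0.02, 5))
  e <- mr_raps(h, loss = "l2", overdispersion = FALSE)
  expect_equal(e$beta, 0.4, tolerance = 1e-8)
  e2 <- mr_raps(h, loss = "huber", overdispersion = TRUE)
  expect_equal(e2$beta, 0.4, tolerance = 1e-6)
  expect_equal(e2$overdispersion_tau2, 0)

  for (seed in 1:10) {
    h <- withr::with_seed(seed, {
      bx <- rnorm(10, 0.2, 0.05)
      harm_fixture(bx, by = 0.25 * bx + rnorm(10, 0, 0.02),
                   sx = runif(10, 0.005, 0.02), sy = runif(10, 0.01, 0.03))
    })
    got <- mr_raps(h, loss = "l2", overdispersion = FALSE)$beta
    want <- oracle_raps_grid(h$beta_exposure, h$beta_outcome,
                             h$se_exposure, h$se_outcome)
    expect_equal(got, want, tolerance = 1e-4)
  }
  expect_error(mr_raps(h[1:2, ]), class = "metabomr_data_error")
})

test_that("odds-ratio conversion exponentiates the estimate and CI", {
  null <- mr_ivw(tibble::tibble(variant_id = c("a", "b"),
                                beta_ratio = c(0, 0), se_ratio = c(0.1, 0.1),
                                weight = c(100, 100)), model = "fixed")
  or <- mr_to_or(null)
  expect_equal(or$or, 1)
  expect_equal(or$or_ci_low * or$or_ci_high, 1)  # symmetric about 1 on log scale

  # headline-style row: beta = log(1.09) with CI (1.06, 1.12)
  se <- (log(1.12) - log(1.06)) / (2 * 1.959964)
  est <- tibble::tibble(beta = log(1.09), se = se)
  or2 <- mr_to_or(est)
  expect_equal(round(or2$or, 2), 1.09)
  expect_equal(round(or2$or_ci_low, 2), 1.06)
  expect_equal(round(or2$or_ci_high, 2), 1.12)

  or3 <- mr_to_or(tibble::tibble(beta = log(2), se = 0))
  expect_equal(unlist(or3), c(or = 2, or_ci_low = 2, or_ci_high = 2))
})

test_that("estimators are equivariant under exposure and outcome negation", {
  h <- withr::with_seed(21, harm_fixture(
    bx = rnorm(12, 0.2, 0.05), by = rnorm(12, 0.05, 0.03),
    sx = runif(12, 0.005, 0.02), sy = runif(12, 0.01, 0.03)))
  # allele flip: both betas negate, estimates unchanged
  hx <- h; hx$beta_exposure <- -h$beta_exposure; hx$beta_outcome <- -h$beta_outcome
  # outcome negation: causal estimates negate
  hy <- h; hy$beta_outcome <- -h$beta_outcome

  for (fn in list(
    function(z) mr_ivw(wald_ratios(z), model = "fixed"),
    function(z) mr_weighted_median(wald_ratios(z), n_boot = 20),
    function(z) mr_egger(z),
    function(z) mr_raps(z, loss = "l2", overdispersion = FALSE)
  )) {
    e <- fn(h); ex <- fn(hx); ey <- fn(hy)
    expect_equal(ex$beta, e$beta)
    expect_equal(ey$beta, -e$beta)
  }
})

test_that("IVW type-I error under the null is within exact binomial bounds", {
  n_rep <- 2000
  tr <- simulation_truth(true_beta = 0, n_instruments = 50,
                         swap_fraction = 0, palindromic_fraction = 0)
  rejects <- vapply(seq_len(n_rep), function(i) {
    tr$seed <- 20000 + i
    sim <- simulate_gwas_pair(tr)
    mr_ivw(wald_ratios(harm_direct(sim)))$pval < 0.05
  }, logical(1))
  bounds <- qbinom(c(0.025, 0.975), n_rep, 0.05)
  expect_gte(sum(rejects), bounds[1])
  expect_lte(sum(rejects), bounds[2])
})

test_that("the fitted battery carries tidy, glance and forest-plot methods", {
  sim <- simulate_gwas_pair(simulation_truth(true_beta = 0.2, seed = 7))
  fit <- mr_fit(harmonize(sim$exposure, sim$outcome), n_boot = 100)
  td <- tidy(fit)
  expect_setequal(td$method,
                  c("IVW_fixed", "weighted_median", "MR_RAPS", "MR_Egger"))
  expect_true(all(td$ci_low <= td$beta & td$beta <= td$ci_high))
  gl <- glance(fit)
  expect_equal(gl$beta_ivw, td$beta[grepl("IVW", td$method)])
  expect_s3_class(autoplot(fit), "ggplot")
})
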