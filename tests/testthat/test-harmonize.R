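test_that("aligned and swapped allele pairs harmonize as expected", {
  exp <- assoc_fixture("rs1", effect_allele = "A", other_allele = "G",
                       beta = 0.1)
  out_same <- assoc_fixture("rs1", effect_allele = "A", other_allele = "G",
                            beta = 0.05, se = 0.02)
  h <- harmonize(exp, out_same)
  expect_equal(h$beta_outcome, 0.05)
  expect_equal(h$action_taken, "aligned")

  out_swap <- assoc_fixture("rs1", effect_allele = "G", other_allele = "A",
                            eaf = 0.7, beta = 0.05, se = 0.02)
  h <- harmonize(exp, out_swap)
  expect_equal(h$beta_outcome, -0.05)
  expect_equal(h$action_taken, "flipped")

  out_bad <- assoc_fixture("rs1", effect_allele = "A", other_allele = "C",
                           beta = 0.05)
  h <- harmonize(exp, out_bad)
  expect_equal(nrow(h), 0)
  expect_equal(attr(h, "dropped")$reason, "allele mismatch")
})

test_that("palindromic variants near eaf 0.5 are dropped, others oriented by frequency", {
  exp_mid <- assoc_fixture("rs1", effect_allele = "A", other_allele = "T",
                           eaf = 0.50)
  out <- assoc_fixture("rs1", effect_allele = "A", other_allele = "T",
                       eaf = 0.50, beta = 0.05)
  h <- harmonize(exp_mid, out, palindromic_eaf_window = 0.08)
  expect_equal(nrow(h), 0)
  expect_equal(attr(h, "dropped")$reason, "palindromic near 0.5")

  # missing eaf on a palindromic variant cannot be oriented: dropped
  exp_na <- assoc_fixture("rs1", effect_allele = "C", other_allele = "G",
                          eaf = NA_real_)
  expect_equal(nrow(harmonize(exp_na, out)), 0)

  # clear frequencies on the same side: aligned as-is
  exp_lo <- assoc_fixture("rs1", effect_allele = "A", other_allele = "T",
                          eaf = 0.2)
  out_lo <- assoc_fixture("rs1", effect_allele = "A", other_allele = "T",
                          eaf = 0.22, beta = 0.05)
  h <- harmonize(exp_lo, out_lo)
  expect_equal(h$beta_outcome, 0.05)

  # frequencies on opposite sides: the outcome is on the other strand
  out_hi <- assoc_fixture("rs1", effect_allele = "A", other_allele = "T",
                          eaf = 0.8, beta = 0.05)
  h <- harmonize(exp_lo, out_hi)
  expect_equal(h$beta_outcome, -0.05)
  expect_equal(h$action_taken, "flipped")
})

test_that("harmonization matches the hand-written allele truth table", {
  bases <- c("A", "C", "G", "T")
  pairs <- expand.grid(ea = bases, oa = bases, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$ea != pairs$oa, ]
  pal <- function(a, b) (a == "A" & b == "T") | (a == "T" & b == "A") |
    (a == "C" & b == "G") | (a == "G" & b == "C")
  # restrict to non-palindromic exposure pairs: palindromic cases are
  # frequency-driven and covered above
  xp <- pairs[!pal(pairs$ea, pairs$oa), ]
  for (i in seq_len(nrow(xp))) {
    for (j in seq_len(nrow(pairs))) {
      if (pal(pairs$ea[j], pairs$oa[j])) next
      exp <- assoc_fixture("rs1", effect_allele = xp$ea[i],
                           other_allele = xp$oa[i], beta = 0.1)
      out <- assoc_fixture("rs1", effect_allele = pairs$ea[j],
                           other_allele = pairs$oa[j], eaf = 0.3, beta = 0.05)
      h <- harmonize(exp, out)
      want <- oracle_allele_action(xp$ea[i], xp$oa[i], pairs$ea[j], pairs$oa[j])
      if (want == "mismatch") {
        expect_equal(nrow(h), 0)
      } else {
        expect_equal(h$action_taken, want)
        expect_equal(h$beta_outcome, if (want == "flipped") -0.05 else 0.05)
      }
    }
  }
})

test_that("harmonization is involutive on an already-aligned pair", {
  sim <- simulate_gwas_pair(simulation_truth(true_beta = 0.1, seed = 3))
  h1 <- harmonize(sim$exposure, sim$outcome)
  # rebuild an outcome table already on the exposure's alleles
  aligned <- sim$exposure[match(h1$variant_id, sim$exposure$variant_id), ]
  aligned$beta <- h1$beta_outcome
  aligned$se <- h1$se_outcome
  h2 <- harmonize(sim$exposure[sim$exposure$variant_id %in% h1$variant_id, ],
                  aligned)
  expect_true(all(h2$action_taken == "aligned"))
  expect_equal(h2$beta_outcome, h1$beta_outcome)
})

test_that("flipping all outcome alleles and beta signs leaves estimates unchanged", {
  sim <- simulate_gwas_pair(simulation_truth(true_beta = 0.15, seed = 11))
  flipped <- sim$outcome
  ea <- flipped$effect_allele
  flipped$effect_allele <- flipped$other_allele
  flipped$other_allele <- ea
  flipped$beta <- -flipped$beta
  flipped$eaf <- 1 - flipped$eaf
  h1 <- harmonize(sim$exposure, sim$outcome)
  h2 <- harmonize(sim$exposure, flipped)
  expect_equal(sort(h1$variant_id), sort(h2$variant_id))
  r1 <- wald_ratios(h1[order(h1$variant_id), ])
  r2 <- wald_ratios(h2[order(h2$variant_id), ])
  e1 <- mr_ivw(r1); e2 <- mr_ivw(r2)
  expect_equal(e1$beta, e2$beta)
  expect_equal(e1$se, e2$se)
})

test_that("proxy search honours the threshold and breaks ties deterministically", {
  ids <- c("rs_t", "rs_a", "rs_b", "rs_c")
  ld <- diag(1, 4); dimnames(ld) <- list(ids, ids)
  ld["rs_t", "rs_a"] <- ld["rs_a", "rs_t"] <- 0.9
  ld["rs_t", "rs_b"] <- ld["rs_b", "rs_t"] <- 0.85
  ld["rs_t", "rs_c"] <- ld["rs_c", "rs_t"] <- 0.5
  cand <- assoc_fixture(c("rs_a", "rs_b", "rs_c"), pos = c(1, 2, 3) * 1000)

  expect_equal(find_proxy("rs_t", ld, cand), "rs_a")
  # strict threshold: nothing above 0.8 -> none
  ld2 <- ld; ld2["rs_t", c("rs_a", "rs_b")] <- c(0.8, 0.7)
  ld2[c("rs_a", "rs_b"), "rs_t"] <- c(0.8, 0.7)
  expect_true(is.na(find_proxy("rs_t", ld2, cand)))
  # exact tie: lexicographically smaller id, regardless of candidate order
  ld3 <- ld; ld3["rs_t", c("rs_a", "rs_b")] <- 0.9
  ld3[c("rs_a", "rs_b"), "rs_t"] <- 0.9
  for (ord in list(1:3, 3:1, c(2, 1, 3))) {
    expect_equal(find_proxy("rs_t", ld3, cand[ord, ]), "rs_a")
  }
  expect_error(find_proxy("rs_missing", ld, cand),
               class = "metabomr_data_error")
})

test_that("harmonize substitutes proxies for instruments absent from the outcome", {
  exp <- assoc_fixture(c("rs_t", "rs_p", "rs_o"), pos = c(1, 2, 5000) * 1000,
                       beta = c(0.1, 0.11, 0.2))
  out <- assoc_fixture(c("rs_p", "rs_o"), pos = c(2, 5000) * 1000,
                       beta = c(0.05, 0.1))
  ids <- c("rs_t", "rs_p", "rs_o")
  ld <- diag(1, 3); dimnames(ld) <- list(ids, ids)
  ld["rs_t", "rs_p"] <- ld["rs_p", "rs_t"] <- 0.95

  h <- harmonize(exp[1, ], out, ld = ld, proxy_source = exp)
  expect_equal(h$variant_id, "rs_p")
  expect_equal(h$action_taken, "proxy_substituted")
  expect_equal(h$beta_exposure, 0.11)  # the proxy's own exposure effect
  # a variant already serving as an instrument is never reused as a proxy
  h3 <- harmonize(exp[1:2, ], out, ld = ld, proxy_source = exp)
  expect_equal(h3$variant_id, "rs_p")
  expect_true("rs_t" %in% attr(h3, "dropped")$variant_id)
  # without LD information the instrument is simply dropped
  h2 <- harmonize(exp[1, ], out)
  expect_equal(nrow(h2), 0)
  expect_equal(attr(h2, "dropped")$reason, "absent from outcome")
})
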