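ICD_CHAPTERS <- c(
  "infectious diseases", "neoplasms", "endocrine/metabolic",
  "hematopoietic", "mental disorders", "neurological", "sense organs",
  "circulatory system", "respiratory", "digestive", "genitourinary",
  "dermatologic", "musculoskeletal", "congenital anomalies", "symptoms",
  "injuries and poisonings"
)

#' Ground-truth parameters for a synthetic two-sample GWAS panel
#'
#' Collects the generating parameters behind one exposure/outcome pair of
#' summary-statistics tables, so simulations are reproducible and recovery
#' tests can compare estimates against the truth. Defaults emulate the scale
#' of published blood-metabolite GWAS (tens of thousands of participants, a
#' per-SD continuous exposure) paired with a large binary case-control
#' outcome GWAS on the log-odds scale.
#'
#' @param true_beta Causal log-odds effect per SD of the exposure; default 0.
#' @param pleiotropy_mode `"none"`, `"balanced"` (invalid instruments get
#'   direct effects centred at zero) or `"directional"` (centred at
#'   `pleiotropy_mean`).
#' @param invalid_fraction Fraction of instruments with direct (pleiotropic)
#'   outcome effects, in \[0, 1\].
#' @param pleiotropy_sd,pleiotropy_mean Spread and (directional) centre of the
#'   per-instrument direct effects.
#' @param n_instruments Number of independent instruments; default 50.
#' @param n_exposure Exposure GWAS sample size; default 24925.
#' @param n_outcome Outcome GWAS total sample size; default 228951.
#' @param case_fraction Case fraction of the binary outcome GWAS; default
#'   122977 / 228951.
#' @param outcome_type `"binary"` (default) or `"continuous"`.
#' @param maf_range Range of minor-allele frequencies; default c(0.05, 0.5).
#' @param exposure_r2_total Total exposure variance explained by the
#'   instruments; default 0.10.
#' @param palindromic_fraction Fraction of instruments given A/T or C/G
#'   allele pairs; default 0.15.
#' @param swap_fraction Fraction of outcome rows stored with swapped alleles
#'   (and sign-flipped beta), exercising harmonization; default 0.3.
#' @param seed Integer seed; required for reproducibility.
#' @return A list of class `simulation_truth`.
#' @export
simulation_truth <- function(true_beta = 0,
                             pleiotropy_mode = c("none", "balanced", "directional"),
                             invalid_fraction = 0,
                             pleiotropy_sd = 0.05,
                             pleiotropy_mean = 0.1,
                             n_instruments = 50,
                             n_exposure = 24925,
                             n_outcome = 228951,
                             case_fraction = 122977 / 228951,
                             outcome_type = c("binary", "continuous"),
                             maf_range = c(0.05, 0.5),
                             exposure_r2_total = 0.10,
                             palindromic_fraction = 0.15,
                             swap_fraction = 0.3,
                             seed = 1) {
  pleiotropy_mode <- arg_match(pleiotropy_mode)
  outcome_type <- arg_match(outcome_type)
  if (invalid_fraction < 0 || invalid_fraction > 1) {
    abort("invalid_fraction must lie in [0, 1]",
          class = "metabomr_parameter_error")
  }
  if (exposure_r2_total <= 0 || exposure_r2_total >= 1) {
    abort("exposure_r2_total must lie in (0, 1)",
          class = "metabomr_parameter_error")
  }
  if (n_exposure < 2 || n_outcome < 2) {
    abort("sample sizes must be at least 2", class = "metabomr_parameter_error")
  }
  if (n_instruments < 1) {
    abort("need at least one instrument", class = "metabomr_parameter_error")
  }
  structure(
    list(true_beta = true_beta, pleiotropy_mode = pleiotropy_mode,
         invalid_fraction = invalid_fraction, pleiotropy_sd = pleiotropy_sd,
         pleiotropy_mean = pleiotropy_mean, n_instruments = n_instruments,
         n_exposure = n_exposure, n_outcome = n_outcome,
         case_fraction = case_fraction, outcome_type = outcome_type,
         maf_range = maf_range, exposure_r2_total = exposure_r2_total,
         palindromic_fraction = palindromic_fraction,
         swap_fraction = swap_fraction, seed = as.integer(seed)),
    class = "simulation_truth"
  )
}

draw_alleles <- function(k, palindromic_fraction) {
  pairs_pal <- list(c("A", "T"), c("C", "G"))
  pairs_reg <- list(c("A", "G"), c("A", "C"), c("T", "G"), c("T", "C"))
  pal <- runif(k) < palindromic_fraction
  purrr::map(pal, function(p) {
    pool <- if (p) pairs_pal else pairs_reg
    pr <- pool[[sample.int(length(pool), 1)]]
    if (runif(1) < 0.5) rev(pr) else pr
  })
}

outcome_se <- function(maf, truth) {
  if (truth$outcome_type == "binary") {
    phi <- truth$case_fraction
    1 / sqrt(2 * maf * (1 - maf) * truth$n_outcome * phi * (1 - phi))
  } else {
    1 / sqrt(2 * maf * (1 - maf) * truth$n_outcome)
  }
}

assoc_row_tbl <- function(ids, chrom, pos, alleles, eaf, beta, se, n) {
  tibble(
    variant_id = ids, chrom = chrom, pos = pos,
    effect_allele = purrr::map_chr(alleles, 1),
    other_allele = purrr::map_chr(alleles, 2),
    eaf = eaf, beta = beta, se = se,
    pval = pmax(2 * pnorm(-abs(beta / se)), .Machine$double.xmin),
    n = n
  )
}

# variant metadata bundle shared between exposure and outcome tables
draw_variant_meta <- function(truth, id_prefix = "rs") {
  k <- truth$n_instruments
  maf <- runif(k, truth$maf_range[1], truth$maf_range[2])
  # effect alleles follow the exposure-increasing orientation convention, so
  # true instrument effects are positive (directional pleiotropy can then
  # act in a consistent direction relative to the instruments)
  g_raw <- abs(rnorm(k))
  scale <- sqrt(truth$exposure_r2_total / sum(2 * maf * (1 - maf) * g_raw^2))
  list(
    ids = sprintf("%s%05d", id_prefix, seq_len(k)),
    chrom = as.character(rep_len(1:22, k)),
    pos = 1e6 + (seq_len(k) %/% 22) * 1e7 + (seq_len(k) %% 22) * 13,
    alleles = draw_alleles(k, truth$palindromic_fraction),
    maf = maf, gamma = g_raw * scale
  )
}

exposure_table <- function(vm, truth) {
  se_x <- 1 / sqrt(2 * vm$maf * (1 - vm$maf) * truth$n_exposure)
  tab <- assoc_row_tbl(vm$ids, vm$chrom, vm$pos, vm$alleles, vm$maf,
                       vm$gamma + rnorm(length(vm$gamma), 0, se_x), se_x,
                       truth$n_exposure)
  attr(tab, "trait_type") <- "continuous"
  tab
}

# outcome table over the given variants; truth$true_beta is the causal effect
outcome_table <- function(vm, truth) {
  k <- length(vm$ids)
  se_y <- outcome_se(vm$maf, truth)
  ob <- simulate_outcome_betas(vm$gamma, truth)
  beta_y <- ob$mean + rnorm(k, 0, se_y)
  swap <- runif(k) < truth$swap_fraction
  alleles_y <- purrr::map2(vm$alleles, swap, function(a, s) if (s) rev(a) else a)
  tab <- assoc_row_tbl(vm$ids, vm$chrom, vm$pos, alleles_y,
                       ifelse(swap, 1 - vm$maf, vm$maf),
                       ifelse(swap, -beta_y, beta_y), se_y, truth$n_outcome)
  attr(tab, "trait_type") <- truth$outcome_type
  attr(tab, "alpha") <- ob$alpha
  tab
}

simulate_outcome_betas <- function(gamma, truth) {
  k <- length(gamma)
  n_invalid <- round(truth$invalid_fraction * k)
  alpha <- numeric(k)
  if (n_invalid > 0 && truth$pleiotropy_mode != "none") {
    idx <- seq_len(n_invalid)   # instruments are exchangeable
    mu <- if (truth$pleiotropy_mode == "directional") truth$pleiotropy_mean else 0
    alpha[idx] <- rnorm(n_invalid, mu, truth$pleiotropy_sd)
  }
  list(mean = truth$true_beta * gamma + alpha, alpha = alpha)
}

#' Simulate an exposure/outcome pair of GWAS summary-statistics tables
#'
#' Generates `n_instruments` independent variants (spread across chromosomes,
#' far apart on the genome): minor-allele frequencies uniform on `maf_range`;
#' true per-SD exposure effects scaled so the total explained variance
#' `sum(2 f (1 - f) gamma^2)` equals `exposure_r2_total`; exposure standard
#' errors `1 / sqrt(2 f (1 - f) n_exposure)`; outcome standard errors
#' analogous on the log-odds scale (with the case-fraction factor for binary
#' outcomes). Observed betas add sampling noise at those standard errors, and
#' invalid instruments add direct pleiotropic effects per the truth object.
#' A fraction of outcome rows is stored with swapped alleles, and a fraction
#' of variants is palindromic, so harmonization is exercised end to end.
#'
#' @param truth A [simulation_truth()] object.
#' @return A list with `exposure` and `outcome` association tibbles, the
#'   per-variant truth table `variants` (true `gamma`, pleiotropic `alpha`)
#'   and the `truth` object itself.
#' @export
simulate_gwas_pair <- function(truth) {
  stopifnot(inherits(truth, "simulation_truth"))
  with_local_seed(truth$seed, simulate_gwas_pair_impl(truth))
}

simulate_gwas_pair_impl <- function(truth, id_prefix = "rs") {
  vm <- draw_variant_meta(truth, id_prefix)
  exposure <- exposure_table(vm, truth)
  outcome <- outcome_table(vm, truth)
  list(exposure = exposure, outcome = outcome,
       variants = tibble(variant_id = vm$ids, maf = vm$maf, gamma = vm$gamma,
                         alpha = attr(outcome, "alpha")),
       truth = truth)
}

make_phenome_catalog <- function(n_phenotypes, catalog_quirks, n_causal) {
  phecodes <- sprintf("%05.1f", seq_len(n_phenotypes) * 2 + 7)
  quirk <- rep("clean", n_phenotypes)
  quirk_slots <- sample(n_phenotypes)
  nq <- c(sex_specific = catalog_quirks$n_sex_specific,
          small = catalog_quirks$n_small,
          redundant = catalog_quirks$n_redundant)
  at <- 1
  for (qn in names(nq)) {
    if (nq[[qn]] > 0) {
      quirk[quirk_slots[at:(at + nq[[qn]] - 1)]] <- qn
      at <- at + nq[[qn]]
    }
  }
  causal_idx <- sample(which(quirk == "clean"), n_causal)
  clean_codes <- phecodes[quirk == "clean"]
  n_cases <- ifelse(quirk == "small",
                    sample(100:499, n_phenotypes, replace = TRUE),
                    sample(2000:50000, n_phenotypes, replace = TRUE))
  catalog <- tibble(
    phecode = phecodes,
    label = sprintf("synthetic trait %03d", seq_len(n_phenotypes)),
    icd_chapter = sample(ICD_CHAPTERS, n_phenotypes, replace = TRUE),
    n_cases = as.integer(n_cases),
    n_controls = as.integer(408961 - n_cases),
    sex_specific = quirk == "sex_specific",
    redundant_of = ifelse(quirk == "redundant",
                          sample(clean_codes, n_phenotypes, replace = TRUE),
                          NA_character_)
  )
  list(catalog = catalog, causal_idx = causal_idx)
}

#' Simulate a block-diagonal LD panel with co-located associations
#'
#' Builds an LD matrix of squared correlations that is constant within each
#' block and zero across blocks, with base-pair positions placing blocks
#' inside or beyond a clumping window as specified, plus matching association
#' rows whose p-values ascend within each block (so greedy clumping has a
#' unique, known answer).
#'
#' @param blocks A list of blocks, each a list with `n_snps`, `r2`
#'   (within-block squared correlation), and optionally `chrom` (default
#'   `"1"`), `start_pos` and `spacing` (bp between adjacent variants, default
#'   1000).
#' @param seed Integer seed (association noise only); default 1.
#' @return A list with `ld` (matrix with dimnames) and `assoc` (tibble).
#' @export
simulate_ld_block <- function(blocks, seed = 1) {
  for (b in blocks) {
    if (b$r2 < 0 || b$r2 > 1) {
      abort("within-block r-squared must lie in [0, 1]",
            class = "metabomr_parameter_error")
    }
  }
  with_local_seed(seed, {
    offset <- 0
    ids_all <- character(); rows <- list(); mats <- list()
    default_start <- 1e6
    for (bi in seq_along(blocks)) {
      b <- blocks[[bi]]
      k <- b$n_snps
      ids <- sprintf("rsb%02d_%03d", bi, seq_len(k))
      chrom <- b$chrom %||% "1"
      start <- b$start_pos %||% default_start
      spacing <- b$spacing %||% 1000
      pos <- start + (seq_len(k) - 1) * spacing
      default_start <- max(pos) + 2e6
      se <- 0.01
      pval <- 10^(-(12 - seq_len(k)))      # ascending p within block
      beta <- se * qnorm(1 - pval / 2)
      maf <- runif(k, 0.2, 0.45)
      alleles <- purrr::map(seq_len(k), ~ c("A", "G"))
      rows[[bi]] <- assoc_row_tbl(ids, rep(chrom, k), pos, alleles, maf,
                                  beta, rep(se, k), 10000)
      rows[[bi]]$pval <- pval
      m <- matrix(b$r2, k, k); diag(m) <- 1
      mats[[bi]] <- m
      ids_all <- c(ids_all, ids)
    }
    n <- length(ids_all)
    ld <- matrix(0, n, n, dimnames = list(ids_all, ids_all))
    at <- 1
    for (m in mats) {
      k <- nrow(m)
      ld[at:(at + k - 1), at:(at + k - 1)] <- m
      at <- at + k
    }
    list(ld = ld, assoc = bind_rows(rows))
  })
}

#' Simulate a phenome of binary outcome panels with a phenotype catalog
#'
#' Generates one shared exposure instrument panel and, for every phenotype in
#' the catalog, an outcome summary-statistics table built on the same
#' variants. A configurable number of catalog entries are flagged
#' sex-specific, given fewer than 500 cases, or marked redundant, so the
#' catalog filter can be exercised; causal phenotypes are always placed among
#' the clean entries. Per-phenotype true effects for the `n_causal` causal
#' phenotypes are drawn uniformly from `effect_range` with random sign.
#'
#' @param n_phenotypes Catalog size; default 50.
#' @param n_causal Number of phenotypes truly affected by the exposure.
#' @param effect_range Absolute causal effect range (log-odds per SD).
#' @param catalog_quirks List with counts `n_sex_specific`, `n_small`,
#'   `n_redundant`.
#' @param truth Template [simulation_truth()]; its `true_beta` is overridden
#'   per phenotype and its seed governs the whole phenome.
#' @param seed Integer seed.
#' @return A list with `catalog` (tibble of phenotype entries), `exposure`
#'   (shared instrument table), `outcomes` (named list of association tibbles
#'   keyed by phecode) and `truth_map` (tibble phecode / true_beta).
#' @export
simulate_phenome <- function(n_phenotypes = 50, n_causal = 3,
                             effect_range = c(0.1, 0.3),
                             catalog_quirks = list(n_sex_specific = 2,
                                                   n_small = 3,
                                                   n_redundant = 1),
                             truth = simulation_truth(),
                             seed = 1) {
  if (n_causal > n_phenotypes) {
    abort("n_causal cannot exceed n_phenotypes",
          class = "metabomr_parameter_error")
  }
  n_quirky <- catalog_quirks$n_sex_specific + catalog_quirks$n_small +
    catalog_quirks$n_redundant
  if (n_quirky + n_causal > n_phenotypes) {
    abort("catalog quirks plus causal phenotypes exceed the catalog size",
          class = "metabomr_parameter_error")
  }
  with_local_seed(seed, {
    # shared exposure panel: same gamma/maf reused by every outcome
    vm <- draw_variant_meta(truth)
    exposure <- exposure_table(vm, truth)

    cat_parts <- make_phenome_catalog(n_phenotypes, catalog_quirks, n_causal)
    catalog <- cat_parts$catalog
    true_beta <- numeric(n_phenotypes)
    true_beta[cat_parts$causal_idx] <-
      runif(n_causal, effect_range[1], effect_range[2]) *
      sample(c(-1, 1), n_causal, replace = TRUE)

    outcomes <- vector("list", n_phenotypes)
    names(outcomes) <- catalog$phecode
    for (i in seq_len(n_phenotypes)) {
      tr <- truth
      tr$true_beta <- true_beta[i]
      tr$n_outcome <- catalog$n_cases[i] + catalog$n_controls[i]
      tr$case_fraction <- catalog$n_cases[i] / tr$n_outcome
      tr$outcome_type <- "binary"
      outcomes[[i]] <- outcome_table(vm, tr)
    }

    list(catalog = catalog, exposure = exposure, outcomes = outcomes,
         truth_map = tibble(phecode = catalog$phecode, true_beta = true_beta),
         variants = tibble(variant_id = vm$ids, maf = vm$maf, gamma = vm$gamma))
  })
}
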