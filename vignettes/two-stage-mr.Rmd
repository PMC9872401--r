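---
title: "Two-stage metabolome-wide and phenome-wide Mendelian randomization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-stage metabolome-wide and phenome-wide Mendelian randomization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(metabomr)
```

## The design

Mendelian randomization (MR) uses genetic variants as instrumental variables
for a modifiable exposure. Because alleles are assorted at conception,
variant–outcome associations are protected from the confounding and reverse
causation that plague observational metabolite–disease associations. In the
two-sample form used here, everything is computed from GWAS summary
statistics: per-variant effect sizes, standard errors and p-values from one
cohort for the exposure (a blood metabolite, measured per SD) and from
another for the outcome (a binary disease, on the log-odds scale).

`metabomr` implements a two-stage design:

1. **Stage 1 — metabolome-wide screen.** Every metabolite panel with
   adequate instruments is tested against a primary disease outcome with a
   battery of estimators. Traits passing a Bonferroni threshold by the main
   estimator and a concordance rule across the robust estimators are
   *nominated* as putative causal mediators.
2. **Stage 2 — phenome-wide scan.** Each nominated metabolite is tested
   against every disease in a phenotype (phecode) catalog. Effects are
   rescaled to the metabolite shift that would produce a fixed 10% reduction
   in primary-outcome risk, so side effects of a hypothetical intervention
   are directly comparable: scaled OR above 1 is a deleterious side effect,
   below 1 a beneficial one.

## Instruments

For each metabolite, instruments are variants reaching genome-wide
significance (`p_threshold = 5e-8`, strict) that survive greedy LD clumping:
survivors are visited in order of ascending p-value and accepted unless they
are within ±500 kb (`window_kb`) of an accepted variant on the same
chromosome *and* correlated with it at `r2_clump >= 0.1`. The window is
interpreted as a half-window around each accepted variant; pairs farther
apart are never clumped regardless of correlation. Within a correlated group
this keeps exactly the lowest-p variant.

Panel-level quality control requires the instruments to explain at least
0.5% of the exposure variance and to number at least 3 (both bounds
inclusive, i.e. "less than 0.5%" and "fewer than 3" are excluded). Variance
explained uses the summary-statistic approximation
$r^2_j = F_j / (F_j + n - 2)$ with $F_j = (\beta_j/\mathrm{se}_j)^2$, summed
over the (approximately independent) clumped instruments; the allele-
frequency form $2f(1-f)\beta^2$ is available as a configurable alternative.
Instrument strength is summarised by
$F = R^2 (n - k - 1) / (k (1 - R^2))$, with $F < 10$ flagged weak.

## Harmonization

Exposure and outcome tables are joined on variant id (coordinates are
1-based and carried along, but identity is by id). The outcome effect is
aligned to the exposure effect allele: allele swaps flip the outcome beta
and complement its frequency, and strand flips (A/G reported as T/C) are
resolved by complementing before comparison. Palindromic variants (A/T,
C/G) cannot be strand-resolved from alleles alone; they are dropped when
the exposure effect-allele frequency is missing or within 0.08 of 0.5
(i.e. in (0.42, 0.58)) and otherwise oriented by frequency agreement. This
window is a design choice made once — conservative, and standard practice in
two-sample MR — because allele frequencies near 0.5 cannot distinguish the
two strands reliably. Instruments absent from the outcome study can be
replaced by a proxy in LD ($r^2 > 0.8$, strict; exact ties broken by
lexicographic variant id), with the proxy's own exposure association taken
from a designated source table.

## Estimators

All estimators consume per-instrument Wald ratios
$\hat\beta_j = \beta_{Yj}/\beta_{Xj}$ with first-order standard errors
$\mathrm{se}_j = \mathrm{se}_{Yj}/|\beta_{Xj}|$ (a second-order delta-method
option adds the exposure-uncertainty term) and weights
$w_j = \mathrm{se}_j^{-2}$.

* **IVW** (main): $\hat\beta = \sum w_j \hat\beta_j / \sum w_j$, identical
  to origin-constrained weighted least squares of $\beta_Y$ on $\beta_X$.
  Heterogeneity is measured by Cochran's
  $Q = \sum w_j (\hat\beta_j - \hat\beta)^2$ on $J-1$ df; the quadratic form
  is minimised exactly at the IVW estimate. With `model = "auto"` the
  multiplicative random-effects standard error
  $\mathrm{se}_{\mathrm{fixed}} \cdot \max(1, \sqrt{Q/(J-1)})$ is used when
  $Q$ gives $p < 0.05$ — the operational meaning of "heterogeneity existed"
  — and the fixed-effect error otherwise. Multiplicative (rather than
  additive) inflation is the summary-data MR convention.
* **Weighted median**: the interpolated weighted 50th percentile of the
  ordered ratios ($s_j = \sum_{i \le j} w_i^\ast - w_j^\ast/2$ interpolated
  at 0.5, with normalised weights), consistent while up to half the weight
  is on invalid instruments. Its standard error comes from a parametric
  bootstrap (default 1,000 replicates, seeded, and isolated from the
  caller's RNG stream) resampling each ratio from
  $N(\hat\beta_j, \mathrm{se}_j)$.
* **MR-Egger**: weighted least squares of $\beta_Y$ on $\beta_X$ with an
  unconstrained intercept, instruments oriented to positive exposure
  effects, weights $1/\mathrm{se}_Y^2$. The intercept estimates directional
  pleiotropy; a two-sided intercept $p < 0.05$ is treated as suggestive
  evidence of it. The residual SD is floored at 1 when scaling coefficient
  errors so Egger precision never exceeds the fixed-effect analysis.
* **MR-RAPS**: solves the profile-score equation
  $\sum_j \rho'(t_j)\,\partial t_j/\partial\beta = 0$ with
  $t_j = (\beta_{Yj} - \beta\,\beta_{Xj}) / \sqrt{\mathrm{se}_{Yj}^2 +
  \beta^2 \mathrm{se}_{Xj}^2 + \tau^2}$, which accounts for exposure
  measurement error (hence weak-instrument robustness). The default loss is
  Huber with constant 1.345, down-weighting outlying instruments; squared
  error is available. With overdispersion on (the default), $\tau^2 \ge 0$
  is estimated jointly from the calibration equation
  $\sum_j (\rho'(t_j) t_j - \delta)/s_j^2 = 0$ with
  $\delta = E[\rho'(Z) Z]$ for standard-normal $Z$ ($\delta = 1$ for
  squared error, $2\Phi(1.345) - 1$ for Huber). Standard errors are
  empirical-sandwich; the solver alternates one-dimensional root finds
  starting from the IVW estimate and is deterministic. Huber loss with
  overdispersion is the default because it is the most robust variant; both
  knobs are exposed.

All p-values are two-sided from the normal distribution, the summary-data MR
convention (Egger can use the t reference via `pval_dist = "t"`); 95% CIs
use $z = 1.959964$ throughout. Estimates on the log-odds scale convert to
odds ratios with `mr_to_or()`.

## Multiplicity and nomination

The stage-1 threshold is $\alpha/M$ with $M$ the number of panels actually
screened after QC (e.g. $0.05/112 = 4.46\times10^{-4}$ for a 112-metabolite
panel), recomputed from the data rather than hard-coded. Nomination then
requires concordant sensitivity evidence: weighted median and MR-RAPS both
significant at nominal 0.05 with the same sign as IVW, and an MR-Egger
intercept p of at least 0.05. Nominal 0.05 (not the Bonferroni level) is
used for the robust estimators: they have less power than IVW by design, and
the rule's role is concordance, not discovery. This operational rule is a
design choice of the package and every piece of it is configurable.

The stage-2 threshold divides $\alpha$ by (nominated metabolites ×
retained phenotypes), e.g. $0.05/1358 = 3.68\times10^{-5}$ for 2 × 679. The
denominator is fixed by the study design before estimation, so pairs that
turn out unestimable still count. The catalog filter drops sex-specific
entries, entries with fewer than 500 cases (500 itself is kept), and entries
annotated redundant of a representative phecode; redundancy is consumed as
an annotation because no algorithm for choosing representatives is implied
by the design.

Rescaling: with $\beta_P$ the metabolite's effect on the primary outcome,
the shift producing a risk ratio of `target_rr` (default 0.90) is
$\Delta = \ln(\mathrm{target})/\beta_P$ SD; a disease effect $\beta_D$
becomes $\beta_D \Delta$ with standard error
$\mathrm{se}_D |\Delta|$. Rescaling the primary outcome by its own $\Delta$
returns exactly the target risk ratio, which the tests assert to machine
precision. A scaled OR of exactly 1 is labelled beneficial by default
(configurable), a boundary that occurs only with a zero disease effect.

## The synthetic generator

No GWAS deposits are bundled; the generator produces summary statistics
with known truth so every stage is testable offline. Its defaults were
chosen once to emulate the scale of the real data sources: a continuous
exposure GWAS of 24,925 participants (the mid-sized NMR metabolome GWAS
scale), a binary outcome GWAS of 228,951 with case fraction 122,977/228,951
(large case-control consortium scale), 50 independent instruments, total
exposure variance explained 10% (inside the observed 0.68%–47.25% range for
genetically instrumented metabolites), minor-allele frequencies uniform on
[0.05, 0.5], 15% palindromic variants, and 30% of outcome rows stored with
swapped alleles so harmonization is always exercised.

Per variant: $\mathrm{se}_X = 1/\sqrt{2f(1-f)n_X}$,
$\mathrm{se}_Y = 1/\sqrt{2f(1-f)n_Y\phi(1-\phi)}$ for a binary outcome with
case fraction $\phi$ (binary outcomes are simulated directly on the
log-odds summary scale — two-sample MR consumes nothing else), true
instrument effects drawn half-normal (the exposure-increasing allele
orientation convention) and scaled so $\sum 2f(1-f)\gamma^2$ equals the
target $R^2$, observed effects adding $N(0, \mathrm{se}^2)$ noise. Invalid
instruments add a direct outcome effect $\alpha_j$: balanced pleiotropy
draws $\alpha_j \sim N(0, 0.05^2)$, directional $N(0.1, 0.05^2)$. Exposure
and outcome panels share no samples, matching the two-sample design.

What the generator does *not* emulate: LD between instruments within a
panel (LD enters only through the dedicated block generator used for
clumping tests), allele-frequency differences between cohorts, population
stratification, sample overlap, winner's-curse correlation between the
selection and estimation data, and case-control imbalance effects beyond
the effective-sample-size approximation. Passing tests therefore
demonstrate the estimators and pipeline logic, not robustness to those
real-data features.

## Problem sizes and numerical choices

The simulation studies in the tests and acceptance script use sizes chosen
as the package's own precision/runtime balance: 200 replicates for
parameter-recovery and bias-ordering runs, 500–2,000 for rejection-rate
calibration (binomial bounds are computed exactly for whichever size is
used), and a default end-to-end scenario of 20 metabolites (2 causal at
log-OR 0.2 per SD, acetate-scale) × 50 phenotypes (3 causal at log-OR
0.1–0.3). Root finding uses `uniroot` with interval extension and tolerance
1e-12; the RAPS alternating solver iterates to 1e-10; clumping ties on
p-value break by variant id so results are order-invariant; all
seed-consuming routines restore the caller's RNG state.

## A worked example

```{r example}
sim <- simulate_gwas_pair(simulation_truth(true_beta = 0.2, seed = 7))
fit <- mr_fit(harmonize(sim$exposure, sim$outcome))
tidy(fit)[, c("method", "beta", "se", "pval")]
```

All four estimators recover the generating effect of 0.2 (per SD, log-odds
scale). The full two-stage pipeline runs from a config object:

```{r pipeline, eval = FALSE}
cfg <- run_config(seed = 1)
pipeline_simulate(cfg, dir = "demo")   # write a synthetic input bundle
scr <- pipeline_screen(cfg, dir = "demo")
ph  <- pipeline_phemr(cfg, dir = "demo")
autoplot(scr)                          # Manhattan-style screen overview
autoplot(ph)                           # side-effect profile per metabolite
```

## Known limitations

* Redundancy pruning of the phenotype catalog must be supplied as
  annotations; the package does not derive representative phecodes.
* Proxy lookup requires a user-supplied LD matrix; no reference panel is
  queried.
* No MR-PRESSO, multivariable MR, Steiger filtering or
  contamination-mixture estimators; no conditional/joint instrument
  selection.
* The Egger intercept calibration under heavy balanced pleiotropy is
  slightly anticonservative with normal p-values at moderate instrument
  counts; the t reference is available where finite-sample calibration
  matters.
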