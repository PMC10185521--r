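---
title: "Bidirectional two-sample Mendelian randomization with bimr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bidirectional two-sample Mendelian randomization with bimr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bimr)
```

## The model

Mendelian randomization (MR) uses genetic variants as instrumental
variables to estimate the causal effect of an exposure (here, a serum
protein level such as a matrix metalloproteinase) on an outcome (here, a
disease such as estrogen-receptor-negative breast cancer). A SNP $j$ is a
valid instrument when it (1) is robustly associated with the exposure,
(2) shares no confounder with the exposure-outcome relation, and (3)
affects the outcome only through the exposure. Under those assumptions,
with per-allele exposure effect $\beta_{Xj}$ and outcome effect
$\beta_{Yj}$, every instrument's Wald ratio
$\hat\theta_j = \beta_{Yj} / \beta_{Xj}$ estimates the same causal effect
$\theta$, and the two-sample design lets $\beta_{Xj}$ and $\beta_{Yj}$
come from independent GWAS cohorts, using only published summary
statistics.

Running the analysis in both directions — exposure on outcome, then
outcome on exposure with instruments re-selected from scratch — probes
reverse causation: a protective effect of the protein on disease together
with a null reverse estimate supports the protein as upstream.

## Instrument selection

`select_instruments()` chains four screens, each audited per removal:

* **Significance.** `pval < 5e-8` (strict inequality, matching the
  printed "P < 5e-8" convention).
* **Confounder exclusion.** An explicit SNP-ID list supplied by the user
  (e.g. hits from a phenome-wide lookup of the instruments). A live
  database query is deliberately out of scope; the decision belongs to
  the analyst and an ID list keeps the run reproducible.
* **LD clumping.** Greedy by ascending p-value at `r2 < 0.01` within
  5 Mb, the plink-style convention. LD comes from a user-supplied pair
  table; within-window pairs absent from the table count as $r^2 = 0$
  with a warning, so a truncated LD table degrades loudly, not silently.
* **Instrument strength.** Per SNP, the variance explained
  $R^2 = 2\,\mathrm{EAF}(1-\mathrm{EAF})\beta^2$ and
  $F = (N-2)\,R^2/(1-R^2)$; instruments with $F < 10$ are removed
  (the boundary $F = 10$ is kept).

Analyses with fewer than five instruments are skipped with a recorded
reason rather than estimated — mirroring how underpowered reverse
datasets are handled in practice.

## Harmonization

`harmonize_datasets()` aligns each outcome record to the exposure's
effect allele: matching orientation needs no action; swapped alleles
negate $\beta_{Y}$ and reflect the EAF; alleles matching only after
complementing both outcome alleles are strand flips. A/T and C/G
(palindromic) SNPs cannot be resolved by strand. Two policies are
exposed: `drop_all` removes every palindromic instrument (the
conservative choice used for the forward direction), and
`drop_intermediate` removes only those whose EAF falls inside the
ambiguity window — default (0.42, 0.58), the conventional window — and
orients the rest by EAF agreement. Instruments absent from the outcome
dataset are dropped into the audit (`missing_in_outcome`); no proxy
lookup is attempted. Removal reasons are `palindromic` under `drop_all`
and `palindromic_intermediate_eaf` under the window rule.

Harmonization is idempotent, and a sign flip preserves $|\beta_Y|$ and
its SE exactly; both properties are asserted in the test suite, as is
exact recovery of flips injected by the simulator.

## Estimators

All five standard estimators operate on the harmonized set. Throughout,
the IVW weight of SNP $j$ is $w_j = \beta_{Xj}^2 / se_{Yj}^2$, which is
the first-order delta-method inverse variance of $\hat\theta_j$; the
Wald-ratio SE uses the same first-order convention (exposure-side noise
ignored). With instruments floored at $F \approx 100$ this approximation
attenuates estimates by under 1%, far below sampling error at the
default study sizes.

* **IVW** (primary): $\hat\theta = \sum w_j\hat\theta_j / \sum w_j$,
  identical to the zero-intercept weighted regression of $\beta_Y$ on
  $\beta_X$ with weights $1/se_Y^2$ (the equality of the two routes is
  asserted to 1e-12 in tests). The default effects model is
  multiplicative random effects: the fixed-effect SE is scaled by
  $\max(1, \sqrt{Q/(J-1)})$, so it reduces to fixed effects when there
  is no overdispersion and is mildly conservative otherwise.
* **MR-Egger**: weighted regression with a free intercept after
  orienting every pair so $\beta_X \ge 0$ (the estimate is not invariant
  to per-SNP sign conventions, so a canonical orientation is required).
  The intercept estimates average directional pleiotropy; SEs use the
  residual scale floored at 1 and inference is t-based with $J-2$ df.
* **Weighted median**: linear interpolation of the cumulative
  normalized weight across the ordered ratios at 50%; consistent while
  valid instruments hold a majority of weight.
* **Simple and weighted mode**: the argmax of a normal-kernel density
  over the ratios evaluated at the ratios themselves, bandwidth
  $h = \phi \cdot 0.9\,\min(sd, IQR/1.349)\,J^{-1/5}$ with $\phi = 1$
  by default; the weighted variant uses IVW weights in both the density
  and the spread measures. If all ratios coincide, that value is
  returned directly.

Median and mode SEs come from a seeded parametric bootstrap (default
1000 replicates) that redraws each ratio from a normal with its
delta-method SE and re-applies the estimator with the original weights.
Confidence intervals use the 1.96 normal multiplier except for Egger,
which uses the $t_{J-2}$ quantile. Binary-outcome effects are reported
on both the log-odds and odds-ratio scales.

`run_all_methods()` emits the table rows in the conventional order
(Egger, weighted median, IVW, simple mode, weighted mode), omitting any
method whose instrument-count minimum (3; IVW 2) is unmet; a single
instrument falls back to the Wald ratio.

## Sensitivity diagnostics

* **Cochran's Q / I²** (`cochran_q()`): about the fixed-effect IVW
  estimate ($df = J-1$) or the Egger fit ($df = J-2$);
  $I^2 = \max(0, (Q-df)/Q)$. Both conventions are reported because
  published tables print one Q per method row.
* **Egger intercept test**: two-sided t test of zero average
  directional pleiotropy.
* **MR-PRESSO** (`mr_presso()`): the observed statistic is the
  leave-one-out residual sum
  $\sum_j (\beta_{Yj} - \hat\theta_{(-j)}\beta_{Xj})^2 / se_{Yj}^2$; its
  null distribution is simulated by redrawing both effect vectors from
  their sampling distributions and recomputing the statistic in full.
  Empirical p-values use the add-one rule $(1+k)/(n_{sim}+1)$, so they
  are never zero; per-SNP residual p-values below $\alpha/J$ flag
  outliers. Because the null is simulated conditional on the observed
  effects, the global p is *approximately* uniform with a mild
  conservative tilt (null rejection a little below nominal); the
  acceptance checks assert bounded Kolmogorov-Smirnov distance and a
  calibrated rejection band rather than exact uniformity. The
  distortion-test stage is not implemented; the workflow uses only the
  global and outlier tests.
* **Leave-one-out** (`leave_one_out()`): J re-estimates of the IVW
  effect, flagging any omission whose CI excludes the full-set point
  estimate.

## Pipeline, multiplicity and reporting

`run_direction()` chains selection, gating, harmonization, estimation
and diagnostics; `run_bidirectional()` runs both directions with
instruments re-selected per direction and direction-specific palindrome
policies (forward `drop_all`, reverse `drop_intermediate`).
`classify_significance()` implements the Bonferroni tiers: strong
evidence below $\alpha/n_{tests}$ (0.05/25 = 0.002 under the 25-test
policy), suggestive between that and 0.05. `n_tests` defaults to the
number of analyses in the rendered batch and can be pinned in the
report. `render_report()` writes per-analysis TSVs (methods,
sensitivity, leave-one-out, audit) and a combined `summary.json`;
every random step takes a seed derived from the master seed by a stable
hash of the analysis labels, so identically configured runs are
byte-identical.

## The synthetic-data generator

`simulate_pair()` draws summary statistics directly — no individual-level
genotypes — because two-sample MR consumes nothing else; independent
exposure/outcome noise realizes the non-overlapping-cohorts assumption
exactly. Defaults encode the study conditions the package targets: a
continuous (SD-unit) exposure GWAS of 21,758, a binary outcome GWAS of
127,442 (log-odds effects), 15 instruments, EAF uniform on (0.05, 0.5).
Standard errors follow $se = 1/\sqrt{2\,\mathrm{EAF}(1-\mathrm{EAF})N}$,
the sampling-variance counterpart of the variance-explained formula.
True exposure effects are $b_j \sim N(0, 0.15^2)$ floored in magnitude
at 10 exposure SEs, so every instrument clears the significance and
weak-instrument screens by construction with true $F \approx 100$ or
more — the strength regime of protein-QTL instruments. Pleiotropic
effects $a_j \sim N(\mu_a, \sigma_a^2)$ are added with the configured
probability, *in the exposure-increasing allele coding* (directional
pleiotropy is only meaningful relative to a fixed orientation; drawn
independently of $|b_j|$, the InSIDE condition holds and Egger remains
consistent). Palindromic allele pairs and strand-flipped outcome
encodings are injected at configurable fractions with the truth log
recording every identity. Instruments are LD-independent by placement;
`simulate_ld_blocks()` exists solely to exercise the clumping code.

What the generator does not emulate — and what green tests therefore do
not certify about real data: LD between instruments, winner's curse in
instrument discovery, sample overlap between cohorts, EAF differences
between populations, and violations of InSIDE. Those belong to the
analyst's judgment, not this package's simulations.

## Numerical and design choices

* Strict inequality at the significance boundary; F = 10 kept at the
  strength boundary; p exactly at a Bonferroni threshold falls to the
  weaker tier.
* Greedy p-value-ordered clumping (the field convention; the thresholds,
  not the algorithm, are what published methods sections specify).
* Duplicate LD pairs keep the maximum r² (conservative for clumping).
* Empty harmonization, too-few instruments, and per-method minimums
  degrade to skipped analyses or omitted table rows; batches never
  abort.
* Monte-Carlo p-values are floored at $1/(n_{sim}+1)$; analytic
  p-values are clamped into (0, 1].
* All ratios identical: the mode returns the common value; Q is 0 with
  $I^2 = 0$ and p = 1.
* Continuous-trait effects are treated as SD-unit effects (the usual
  output of rank-based inverse-normal-transformed GWAS); if a source
  reports another unit the estimates scale accordingly.

## Problem sizes used in the checks

The packaged statistical checks run, on one CPU, 1000 null replicates
for type-I-error and Q calibration, 500 replicates for recovery of
$\theta = \ln 0.92$ and CI coverage (observed coverage about 0.95-0.97:
the multiplicative-random floor makes IVW mildly conservative), 200
replicates for the pleiotropy bias ordering (weighted-median bias well
below IVW bias at 30% pleiotropic weight), 100 for Egger intercept
power, and 500 null MR-PRESSO batches at 500 simulations each. These
sizes put Monte-Carlo error comfortably inside the asserted bands while
keeping the whole suite in the minutes range.

## A worked run

```{r example, eval = FALSE}
sim <- simulate_pair(sim_config(n_snps = 15, theta = log(0.92), seed = 42,
                                null_snp_count = 10))
res <- run_direction(sim$exposure, sim$outcome, config = mr_config(seed = 42))
res$estimates[, c("method", "n_snp", "or", "or_low", "or_high", "pval")]
render_report(res, "mr_report", n_tests = 25)
```

With this seed the IVW estimate is OR 0.939 (95% CI 0.926-0.952,
p = 2.6e-19, 15 SNPs) against a generating OR of 0.92; heterogeneity,
Egger-intercept and MR-PRESSO diagnostics are all null, as constructed.

## Limitations

Single-nucleotide A/C/G/T alleles only (no indels — palindrome logic is
undefined for them); no proxy-SNP lookup; no GWAS-VCF parsing or remote
accession fetching; no MR-RAPS, Steiger filtering, or multivariable MR;
leave-one-out re-estimates IVW only. The package analyzes whatever
summary statistics it is given — data provenance, population matching
and unit conventions remain the analyst's responsibility.
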