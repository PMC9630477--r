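---
title: "Methods: two-sample MR screening with mrscreen"
author: "mrscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-sample MR screening with mrscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrscreen)
```

## The problem

`mrscreen` implements a screening pipeline for two-sample Mendelian
randomization (MR): given GWAS summary statistics for a family of exposures
(the motivating application is a panel of immune-cell traits measured in a
cohort of roughly 3,800 individuals) and for one or more outcomes (bone
mineral density at several skeletal sites, from GWAS of roughly 8,000 to
67,000 individuals), it asks whether genetically predicted differences in
each exposure shift the outcome. Genetic variants serve as instrumental
variables: a variant that changes the exposure but affects the outcome only
through it supports a causal interpretation of the exposure–outcome
association.

The package covers the full workflow: instrument selection, allele
harmonization, univariable estimation with a sensitivity suite,
false-discovery-rate control over a structured family of tests,
multivariable MR, and mediation decomposition — together with a synthetic
GWAS generator with known causal structure, so that every stage can be
validated against ground truth at desk scale.

## Instrument selection

Instruments for an exposure are selected in four steps, each of which can
only shrink the set (`select_instruments()`):

1. **Significance.** Variants with exposure `P < 1e-5` (the conventional
   loose threshold for phenotypes with modest GWAS sample sizes). For
   reverse-direction analyses, where the roles of the traits are swapped,
   the genome-wide `5e-8` is used instead.
2. **LD clumping** (`ld_clump()`). Greedy, p-value-ranked: the most
   significant remaining variant becomes an index, and all remaining
   variants on the same chromosome within 500 kb whose sample r² with the
   index (computed from a haplotype reference panel) exceeds the threshold
   (0.1 forward, 0.01 reverse) are removed. Ties on p are broken by
   position and then by variant id, making the result independent of input
   row order.
3. **Harmonization** (`harmonize()`). Outcome effects are aligned to the
   exposure's effect allele, flipping signs and complementing frequencies
   where the allele labels (directly or on the complementary strand) are
   swapped. Palindromic variants (A/T, C/G) cannot be strand-resolved from
   labels; they are aligned by allele frequency when both frequencies are
   informative (outside 0.42–0.58) and concordant (same side of 0.5), and
   dropped otherwise. Incompatible allele pairs and variants absent from
   the outcome are dropped and counted, never fatal.
4. **Strength filtering** (`compute_strength()`). Per variant,
   the proportion of exposure variance explained is
   \( \mathrm{PVE}_j = \frac{2f_j(1-f_j)\hat\beta_j^2}
   {2f_j(1-f_j)\hat\beta_j^2 + 2f_j(1-f_j)\,\mathrm{se}_j^2\,n} \)
   and \( F_j = (n-2)\,\mathrm{PVE}_j/(1-\mathrm{PVE}_j) \); variants with
   \(F_j < 10\) are removed as weak instruments. The retained set reports
   \(R^2=\sum_j \mathrm{PVE}_j\) and
   \(F = \frac{n-k-1}{k}\frac{R^2}{1-R^2}\).

## Estimators

Write \(\hat\lambda_{X,j}, \hat\lambda_{Y,j}\) for the harmonized exposure
and outcome effects of instrument \(j\) and \(\sigma_{Y,j}\) for the outcome
standard error. The per-variant **Wald ratio** is
\(\hat\theta_j = \hat\lambda_{Y,j}/\hat\lambda_{X,j}\) with first-order
delta-method standard error \(\sigma_{Y,j}/|\hat\lambda_{X,j}|\) (a
second-order version including exposure-side noise is available behind the
`second_order` flag of `wald_ratio()`).

- **IVW** (`mr_ivw()`): inverse-variance-weighted mean of the ratios,
  equivalently weighted least squares of outcome on exposure effects
  through the origin with weights \(1/\sigma_{Y,j}^2\). Fixed effects use
  \(\mathrm{SE} = (\sum_j w_j)^{-1/2}\); random effects multiply the SE by
  the over-dispersion scale \(\max(1, \sqrt{Q/(J-1)})\). The default
  `"auto"` mode follows the heterogeneity rule: fixed effects unless
  Cochran's Q has \(p < 0.05\), in which case random effects are used.
- **Cochran's Q** (`cochran_q()`):
  \(Q = \sum_j w_j(\hat\theta_j - \hat\beta_{\mathrm{IVW}})^2\) on \(J-1\)
  degrees of freedom.
- **MR-Egger** (`mr_egger()`): weighted regression *with* intercept after
  orienting exposure effects positive; the intercept estimates average
  directional pleiotropy (its t test on \(J-2\) df is the pleiotropy
  test), and the slope is a pleiotropy-adjusted causal estimate, valid
  when pleiotropic effects are independent of instrument strength
  (InSIDE).
- **Weighted median** (`mr_weighted_median()`): the weighted median of the
  ratios via linear interpolation of the mid-cumulative standardized
  weights at 0.5; consistent when valid instruments carry at least half
  the weight. Its SE comes from a parametric bootstrap (default 1,000
  replicates) redrawing per-variant effects from their estimated normals.
- **MR-PRESSO** (`mr_presso()`): simulation-based global heterogeneity
  test on the weighted leave-one-out residual sum of squares, a per-variant
  outlier test (Bonferroni 0.05/J), and a distortion test comparing the
  outlier-free estimate against random removals of the same size.
  Empirical p-values use the \((1+\#\mathrm{exceedances})/(1+n_\mathrm{sim})\)
  convention; defaults are 1,000 simulations, which bound the smallest
  outlier p at \(1/1001\) — small enough for the Bonferroni level at the
  instrument counts this pipeline produces (tens, not thousands).
- **Cook's distance** (`cooks_exclusion()`): influence of each instrument
  on the weighted IVW regression, with the conventional exclusion
  threshold \(4/J\). Computed via `stats::lm()` + `stats::cooks.distance()`.

P-values for IVW, the weighted median and MVMR use the normal
approximation; MR-Egger uses the t distribution. All intervals are
two-sided at 95% by default. `mr_fit()` bundles the suite into one classed
object; `mr_sensitivity()` adds the diagnostics and re-runs the estimators
with the union of flagged instruments removed (`rerun_after_removal()`),
reporting all diagnostics side by side without imposing a precedence among
them — when the Egger intercept and the PRESSO global test disagree, both
are visible.

## Multiplicity

The screen's primary (IVW) p-values are corrected with Benjamini–Hochberg
FDR **within subgroups**: four immune-trait measurement types (MFI, AC, RC,
MP) crossed with seven immune-cell panels, 28 subgroups in all
(`groupwise_fdr()`). Sensitivity-method p-values are reported unadjusted.
The grouping key is configurable; whether outcomes should additionally
partition the family is left to the caller (the default pools outcomes
within a subgroup, which is the more conservative reading).

## Multivariable MR and mediation

`mvmr_fit()` regresses instrument–outcome effects on the matrix of
instrument–exposure effects without intercept, weights \(1/\sigma_{Y,j}^2\):
\[ \hat\lambda_{Y} = \textstyle\sum_i \hat\lambda_{X_i}\,\beta_i + e,
   \qquad e \sim N(0, \sigma^2), \]
estimated by weighted least squares. Each \(\beta_i\) is a *direct* effect
conditional on the other exposures. SEs carry the same multiplicative
over-dispersion (floored at 1) as random-effect IVW, to which the model
reduces exactly for a single exposure (one shared code path). Collinear
designs raise an error naming the offending columns; the condition number
of the weighted design is always reported.

`mr_mediation()` decomposes the effect of an exposure on an outcome through
a mediator, using **exposure instruments only** (the network-MR
convention): total effect from univariable IVW; direct effect as the
exposure coefficient of the joint exposure+mediator MVMR; indirect effect
by the **difference method**, `total - direct`, so `total = direct +
indirect` holds identically; proportion mediated `indirect/total`
(undefined, not infinite, when the total is numerically zero). The product
estimate \( \hat a \hat b \) — exposure→mediator IVW times the mediator's
joint coefficient — is always reported as a cross-check and can be made the
primary estimator via `method = "product"`. Confidence intervals are
percentile intervals from a parametric bootstrap (default 1,000
replicates) that redraws every per-instrument effect from its estimated
normal; percentile rather than BCa because it is the simplest interval
that is defensible at the summary-statistic level, where no individual
data exist to resample.

## The synthetic generator

`simulate_gwas()` draws, per variant: an allele frequency uniform on
`maf_range`; a true exposure effect \(\gamma_j\) with scale `gamma_sd`; a
pleiotropic outcome effect \(\alpha_j \sim N(\mu_\alpha, \sigma_\alpha^2)\)
on a fraction `invalid_frac` of variants (optionally coupled to
\(\gamma_j\) through `inside_kappa` to violate InSIDE); a true outcome
effect \(\beta\gamma_j + \alpha_j\); and observed marginal effects with the
analytic standardized-GWAS standard error \(1/\sqrt{2n f(1-f)}\), from
which p-values follow the two-sided normal test exactly. Marginal effects
are simulated directly at the summary level — the pipeline consumes only
summary statistics — while LD lives in a separately generated haplotype
panel (`simulate_ld_panel()`): independent blocks in which the allele
correlation at lag \(k\) is exactly \(\rho^k\) (a two-state Markov chain
with second eigenvalue \(\rho\); block-constant allele frequency keeps this
exact). `simulate_mediation_gwas()` adds a mediator with its own
instruments and path coefficients `a`, `b`, `c`, recording
`total = c + a*b` as ground truth.

Default parameters are chosen to emulate the motivating study's data
regime and are deliberately not moved per analysis:

- `n_exp = 3757` (immunophenotype GWAS), `n_out = 66628` (total-body BMD;
  the other skeletal sites ranged down to 8,143, used where a smaller
  outcome GWAS is the scenario of interest, e.g. the outlier-recovery
  checks).
- `gamma_sd = 0.25`, with instrument effects **oriented positive**
  (half-normal). Orientation matters: with zero-mean signed effects and
  pleiotropy independent of them, directional pleiotropy is invisible by
  construction — after the analysis-side orientation that MR-Egger
  performs, the planted mean cancels — so a generator meant to exercise
  pleiotropy diagnostics must plant effects in the oriented frame, as the
  simulation designs in the MR-Egger and weighted-median literature do.
  The scale puts selected instruments (|effect| above ~0.12 at
  `n_exp = 3757` and `P < 1e-5`) in the strong-instrument regime
  (per-instrument F roughly 40–400, per-instrument PVE ~0.5–3.5%), where
  the first-order theory behind the estimators applies.
- `invalid_frac = 0`, `pleio_mean = 0`, `pleio_sd = 0.05` — a valid-IV
  baseline; robustness scenarios switch on 40% invalid instruments with
  directional mean 0.1.
- Mediation defaults `a = 0.8`, `b = 0.5`, `c = 0.1` (total 0.5,
  proportion mediated 0.8), with `med_direct_sd = 0.05` giving exposure
  instruments variant-specific direct effects on the mediator. This
  pathway heterogeneity is what makes the joint exposure+mediator
  regression identifiable from exposure instruments alone: were mediator
  effects exactly proportional to exposure effects, the two columns would
  be structurally collinear.

What the generator does **not** emulate: realistic human LD maps and
allele-frequency spectra, covariate adjustment, sample overlap between the
two GWAS, binary outcomes, or correlation between true effects of variants
sharing an LD block (marginal effects are drawn independently even when
the panel is correlated). Passing tests therefore demonstrate correctness
of the estimators and machinery under the stated generative model, not
robustness to everything real data can do.

## Numerical and design choices

- **Seeds.** Every stochastic function takes a `seed` and is bit-for-bit
  reproducible under it; `run_screen()` seeds once and reproduces
  byte-identical output files.
- **Degenerate inputs.** A single instrument degrades IVW to the Wald
  ratio; a zero exposure effect is an explicit error for `wald_ratio()`
  and removed (zero PVE/F) by the strength filter; an exact-fit regression
  (zero residual) yields zero Cook's distances rather than 0/0; bootstrap
  intervals with all-zero SEs collapse to the point estimate; a
  numerically zero mediation total reports an undefined proportion.
- **Ties.** Clumping breaks p-value ties by position, then id.
- **Problem sizes in the checks.** The verification suite uses 100 random
  oracle instances (J = 3–20), 5,000 null replicates for type-I error,
  500 replicates for the pleiotropy-robustness ordering and Egger power,
  200 for outlier recovery, and 100 for pipeline coverage and mediation
  coverage with the full 1,000-replicate bootstrap — sizes at which the
  binomial noise of each empirical rate is small relative to the margin
  being tested, while the whole suite stays a desk-scale computation.

## Known limitations

- **Winner's curse.** Instruments are selected and estimated in the *same*
  exposure GWAS (as in the motivating study). At `n_exp = 3757` and
  `P < 1e-5`, the selected effects are slightly inflated, attenuating the
  IVW estimate by about 1% of the true effect in the default scenario.
  That bias is invisible to the reported SE, and at the precision provided
  by a 66,628-sample outcome GWAS it costs real CI coverage: empirically
  ~86–90% rather than the nominal 95% for a large effect (β = 0.5). This
  is a property of the design the pipeline reproduces, not of the
  implementation; a three-sample design or shrinkage correction would
  remove it but is out of scope.
- **First-order ratio SEs.** Exposure-side noise is ignored in the
  weights and per-ratio SEs (the cited estimators' standard definitions).
  When the exposure GWAS is much smaller than the outcome GWAS this
  under-states per-ratio uncertainty; the heterogeneity-driven switch to
  multiplicative random effects absorbs most, but not all, of it (the
  over-dispersion scale is itself noisy at small J).
- **Bootstrap scope.** The mediation bootstrap resamples summary-level
  sampling noise only; spread in *true* per-variant pathway effects
  (`med_direct_sd`) is a population quantity that instrument-level
  resampling cannot see, so mediation intervals are mildly anticonservative
  when pathway heterogeneity is large relative to sampling noise.
- **MR-PRESSO resolution.** With 1,000 simulations the smallest
  achievable outlier p-value is 1/1001; for very large instrument sets the
  Bonferroni threshold can fall below it, requiring a larger `n_sim`.

## Reproducing the verification numbers

`scripts/acceptance.R` (repository root) recomputes every quantity above
from scratch against the installed package:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
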