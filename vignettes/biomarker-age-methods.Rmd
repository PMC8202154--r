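---
title: "Biomarker-based biological age: models, assumptions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Biomarker-based biological age: models, assumptions, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bioage)
library(dplyr)
```

## The problem

Chronological age (CA) is the dominant risk factor for most chronic diseases,
but people of the same CA differ in how far their physiology has aged. A
*biological age* (BA) summarises a panel of clinical biomarkers — lung
function, blood pressure, kidney markers, lipids, grip strength and so on —
as the age that the biomarker profile typically reflects. In apparently
healthy middle-aged adults, where disease history carries little information,
BA is a candidate tool for identifying unrecognised risk early enough for
prevention.

`bioage` implements that analysis end to end for right-censored cohort data:

1. a **healthy-subpopulation filter** with an auditable exclusion trail,
2. **varimax-rotated principal components** of the biomarker panel, per sex,
3. a **Klemera–Doubal (KDM) biological age** built on the retained
   components, *without* CA as a constituent biomarker,
4. a **variance decomposition** ranking components by their contribution to
   BA, and
5. a **survival evaluation** of BA versus CA for two outcomes
   (chronic-disease mortality and age-related hospital admission) via nested
   Cox partial likelihoods, Harrell's C-indices, and Kaplan–Meier curves
   across ±5-year age-acceleration groups.

Because cohorts of this kind are access-controlled, the package ships a
synthetic-cohort generator with the statistical structure the analysis
assumes, so every stage is exercised by reproducible tests.

## The component model

Biomarkers are z-scored with means and SDs estimated on the *fit rows* (the
healthy subset of one sex), and the correlation matrix is
eigen-decomposed. Loadings are scaled eigenvectors
($L_{ij} = v_{ij}\sqrt{\lambda_j}$), so the eigenvalues sum to the number of
biomarkers $p$ and average 1. Components with $\lambda_j > 1/3$ — more than
a third of the variation an average biomarker carries — are retained
(strict inequality; the threshold sits on the average-variance scale, which
is why correlation-matrix PCA is forced). Retained loadings are then
varimax-rotated towards simple structure: the rotation maximises the sum
over components of the variance of squared loadings, leaving row
communalities invariant.

Design choices that were genuinely open:

* **Retain-then-rotate.** Rotating only the retained components keeps the
  rotated space identical to the retained space; rotating all $p$ components
  first would mix discarded noise directions into the retained basis.
* **Raw varimax** (no Kaiser row-normalisation) is the default because it is
  the simpler referent; normalisation is exposed as a flag.
* **Sign convention.** Each rotated component is flipped so that its
  largest-|loading| biomarker loads positively. Without this the pipeline
  would be reproducible only up to column signs.
* **Scores.** Rotated scores are computed in the unit-variance basis
  ($z\,V\Lambda^{-1/2}R$), so every retained component enters the next stage
  with fit-sample variance 1 and pairwise correlation 0. Alternative scoring
  conventions differ only by per-component scale, which the KDM age
  regressions absorb (BA is invariant to rescaling any score column — this
  is tested).
* The rotation is delegated to `stats::varimax` (tolerance `1e-8`); on
  inputs where it fails to improve the criterion the identity rotation is
  returned with a warning, preserving the ascent invariant the tests assert.

## The Klemera–Doubal biological age

For each retained component $j$, ordinary least squares of the score on CA
over the fit subset gives intercept $q_j$, slope $k_j$ (per year) and
residual RMSE $s_j$ (denominator $n-2$). The KDM estimator inverts these
regressions and precision-weights them:

$$\mathrm{BA} \;=\; \frac{\sum_j (x_j - q_j)\,k_j/s_j^2}{\sum_j k_j^2/s_j^2},$$

equivalently $\mathrm{BA} = \sum_j w_j (x_j - q_j)$ with
$w_j = (k_j/s_j^2) / \sum_i k_i^2/s_i^2$. The weights satisfy
$\sum_j w_j k_j = 1$ identically, which is the estimator's calibration
property: a profile lying exactly on every regression line at age $a$ yields
$\mathrm{BA} = a$, and on data generated from the model the per-bin mean BA
tracks mean CA (tested at 2.5-year bins, tolerance one year).

CA is deliberately *not* a constituent biomarker, so BA and CA can be
compared as competing predictors downstream. The CA-corrected KDM variant —
which shrinks BA towards CA using $s_{BA}^2 = \max(\mathrm{Var}(BA - CA) -
1/\textstyle\sum_j k_j^2/s_j^2,\, 0)$ — is available behind
`fit_kdm(..., ca_correction = TRUE)` for comparison only.

Components with $|k_j|$ below $10^{-12}$ (or degenerate $s_j$) are dropped
with a warning: they contribute no age signal and would leave their weights
undefined. A perfectly noiseless score ($s_j \to 0$) is likewise flagged
rather than allowed to dominate the weighted sum.

**Importance.** Because retained rotated scores are uncorrelated, the
variance of BA decomposes exactly over components:
$\mathrm{share}_j = w_j^2 \mathrm{Var}(x_j)/\mathrm{Var}(BA)$, summing to 1.
Shares are computed on the fit subset's empirical score variances; with
orthogonal scores this equals the marginal $R^2$ of BA on each score (a
$10^6$-draw Monte-Carlo decomposition is the test oracle).

## Survival evaluation

All survival machinery runs through the `survival` package: Cox fits use
`coxph` with Efron tie handling (day-granularity follow-up produces ties;
Breslow is available via a flag and is what the test suite's grid-search
oracle uses on tie-free fixtures), Kaplan–Meier via `survfit`, log-rank via
`survdiff`, and Harrell's C via `concordance` (tied risk scores credited
0.5; pairs tied on time with both events incomparable).

The quantity of interest is the **proportion of the combined age effect
explained by BA**,

$$\frac{\ell_{BA} - \ell_0}{\ell_{BA+CA} - \ell_0},$$

where $\ell$ are partial log-likelihoods of nested Cox models (null, BA
only, BA + CA) on identical rows. The nesting order
$\ell_{BA+CA} \ge \max(\ell_{BA}, \ell_{CA}) \ge \ell_0$ is asserted on
every evaluation run; a violation beyond $10^{-6}$ aborts rather than
reports, since it indicates an upstream misfit. The ratio is reported
missing when the combined gain is below $10^{-8}$. Other summaries of
"comparing log-likelihoods" (e.g. chi-square shares) exist; this ratio is
the documented, fixed choice.

P-values for adding BA to a CA model come from likelihood-ratio tests
(chi-square, df = added coefficients). C-indices are reported unadjusted and
adjusted for deprivation quintile, smoking, alcohol and assessment centre
(the adjusted C is the C of the full Cox linear predictor). Age-acceleration
groups use closed boundaries: BA − CA ≤ −5 is "younger", ≥ +5 "older".

The **benchmark mortality score** is a forward-stepwise Cox regression on
the component scores against mortality (entry p < 0.05, removal p > 0.10 —
the conventional defaults, since no criterion is canonical), whose linear
predictor is then compared with BA for predicting admissions. With a null
panel the entry rate per candidate is 0.05 by construction (tested by
simulation); note that with many candidates some noise entry is *expected*,
so the planted-signal test asserts that the signal enters first, not that
nothing else ever does.

## What the synthetic cohort emulates

`sim_config()` defaults are a stated world, fixed once:

| quantity | default | rationale |
|---|---|---|
| CA | Uniform(40, 70) y | recruitment age range of the target cohort |
| latent offset $\delta$ | Normal(0, 5²) y | biological-age spread; BA−CA SDs land near 8.5 y |
| panel | 12 biomarkers in 4 blocks of 3 | adiposity / lung / blood-pressure / lipid groups |
| slopes | ±0.024–0.102 units/y, varied | lung strongest (negative), adiposity weakest; calibrated so the healthy-subset KDM $R^2$ vs CA is ≈ 0.50 |
| block correlation | 0.3 | within-panel residual correlation |
| mortality hazard | 0.002/y × e^{0.09·(BA_true − mean)} | ≈1.7% events over ~8.7 y median follow-up in the healthy subset |
| admissions hazard | 0.022/y × e^{0.05·(BA_true − mean)} | ≈16% events over ~8 y |
| censoring | Uniform(6, 12) y | staggered recruitment with a fixed end date |
| eligibility | 6 rules, base failure 0.18, log-odds +0.06/y of $\delta$ | healthy pass fraction ≈ 0.30, failures biologically older |
| sex ratio | 0.54 women | typical of volunteer cohorts |

Event times are exponential given BA_true (no Weibull shape by default:
the flat hazard yields closed-form checks such as the event fraction
$1 - e^{-\lambda t}$); censoring is independent of covariates; the two
outcomes are conditionally independent given BA_true; sexes are simulated as
independent panels so slopes may differ by sex.

What the generator does **not** emulate: the marginal distributions of any
real biomarker panel, ICD-coded outcome definitions, missing data, repeat
measurements, or dependence between the two outcomes beyond the shared
latent age. A green test therefore establishes that the *machinery* is
correct under the assumed structure — linear biomarker–age trends, a single
latent aging factor, proportional hazards — not that the numbers generalise
to any particular cohort.

One structural point the simulation makes visible: with
$\sigma_\delta = 5$ y and CA uniform on 40–70, BA can out-track CA for the
latent age (cor(BA, BA_true) > cor(CA, BA_true)) only when the BA
measurement SD is below $\sqrt{33} \approx 5.8$ y, i.e. when the panel is
strongly informative ($R^2$ vs CA above ≈ 0.56). Real panels reporting
$R^2 \approx 0.44$–$0.51$ sit just below that bar: their BA adds predictive
signal for *outcomes* while remaining a noisier readout of the latent age
than CA itself. The parameter-recovery test therefore uses a deliberately
strong-slope panel, and the package defaults keep the realistic weaker one.

## Numerical choices

* Varimax: tolerance `1e-8` on the criterion, `stats::varimax`'s iteration
  cap; identity fallback on non-improvement.
* Cox: `survival::coxph` defaults (Newton iteration with step halving);
  convergence flagged false when any |coefficient| ≥ 15, the practical
  signature of monotone likelihood.
* OLS age regressions: closed-form sums; $s$ uses denominator $n-2$;
  degenerate slopes/|residuals| below $10^{-12}$ flagged non-informative.
* Calibration bins are left-closed and anchored at `floor(min(ca))` by
  default; empty bins are omitted.
* Acceleration boundaries are closed ("at least 5 years" on both sides).
* Zero-variance biomarkers abort standardization by name; missing values
  abort PCA (imputation is upstream policy, not silently applied).

## Worked example

```{r example, eval = FALSE}
cfg <- pipeline_config(
  sim  = sim_config(n_participants = 20000, seed = 1),
  seed = 1
)
report <- run_pipeline(cfg)
summary_table(report)
plot_calibration(report)
plot_importance(report)
plot_km_acceleration(report, "admissions")

# smaller, more practical panel: biomarkers of the 10 most important components
reduced_panel_analysis(report$strata$F, cfg)$comparison
```

## Known limitations

* The healthy filter's first-failing-rule audit attribution is a reporting
  convention, not identifiable from data in which failures co-occur.
* Proportional hazards are assumed, not tested; no competing risks.
* C-index standard errors are the analytic form from
  `survival::concordance`, not resampled.
* The stepwise benchmark is the conventional forward/backward p-value
  variant; other stepwise flavours would select different sets on
  borderline panels.
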