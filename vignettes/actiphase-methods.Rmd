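---
title: "Methods: activity parameters and discriminant classification of bipolar illness phase"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: activity parameters and discriminant classification of bipolar illness phase}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(actiphase)
```

## The problem

Acutely admitted bipolar-disorder inpatients present in one of three phases —
mania, bipolar depression, or a mixed state — and their daytime motor activity
carries phase information beyond its mean level: how variable it is, how
regular, and how its variance distributes across time scales. `actiphase`
implements a pipeline that takes minute-epoch wrist-actigraphy recordings
(~22 h, typically started mid-day), isolates one sustained **active morning
period** and one **active evening period** of 64 minutes each, summarises each
period with six linear and non-linear activity parameters, and classifies the
illness phase with a canonical discriminant function analysis (DFA), honestly
assessed by leave-one-out cross-validation and a stratified case bootstrap.

Because no patient recordings are publicly available for this design, the
package also ships a synthetic-cohort generator whose extracted features are
calibrated to published phase-specific group estimates; every downstream stage
is tested against it.

## Active-period extraction

The analysis day runs 06:00–24:00 and splits into a morning window
(06:00–15:00) and an evening window (15:00–24:00), half-open so 15:00 belongs
to the evening only. Within a window we search for a contiguous 64-min
segment of sustained activity: at tolerance $k = 2$ a segment may contain no
run of more than two consecutive zero-count minutes; if no 64-min window
anywhere qualifies, the tolerance relaxes to 3, then 4, … (all start
positions are tried at each $k$ before $k$ is raised, so the reported
tolerance is minimal). The morning search runs forward from the start of the
window, the evening search backward from its end (the latest qualifying start
wins). Segment length 64 is a power of two, which the Fourier band analysis
requires. Since $k = 64$ always qualifies, the search terminates.

Two points the search leaves open were decided as follows:

* **Step size** is 1 minute — the finest granularity consistent with
  "first qualifying period".
* **Day selection**: a 22-h recording started at 12:41 covers the morning
  window twice (a partial instance on day 1, 06:00–10:41 on day 2). The
  default rule `prefer_maximal_coverage` uses the instance with more recorded
  minutes (ties to the earlier day), which maximises the chance that the
  64-min search succeeds; `first`/`second` are available as explicit
  alternatives. Gaps in the minute grid are a hard error, not imputed — the
  design assumes continuous recordings.

## The six activity parameters

For a 64-count segment $x_1,\dots,x_{64}$ (counts/min):

| Parameter | Definition | Convention |
|---|---|---|
| `mean_cpm` | $\bar x$ | — |
| `sd_pct` | $100\,s/\bar x$ | sample SD ($n-1$) |
| `rmssd_pct` | $100\sqrt{\tfrac1{63}\sum_t (x_{t+1}-x_t)^2}/\bar x$ | minute-to-minute variability |
| `autocorr_lag1` | $\sum_t \tilde x_t\tilde x_{t+1} / \sum_t \tilde x_t^2$ | correlogram convention (as `stats::acf`); a Pearson-on-pairs variant is selectable |
| `sampen` | $-\ln(A/B)$, $m=2$, $r=0.2$ | series normalised to sample mean 0, variance 1; Chebyshev distance; self-matches excluded; both template sets start at $1..n-m$ |
| `fourier_ratio` | HF/LF band variance | periodogram of the normalised series |

The correlogram autocorrelation was chosen because it is the default in the
mainstream statistics stacks this kind of analysis is run in; its small-sample
bias (about $-1/(n-1)$ under white noise) is verified by a Monte-Carlo test.

**Sample entropy** follows the Richman–Moorman definition exactly: $B$ counts
distinct pairs of length-$m$ templates within tolerance $r$ of each other in
Chebyshev distance, $A$ the same for length $m+1$. If $A$ or $B$ is zero the
statistic is undefined; we flag `NA` and exclude the row (with a report)
rather than substitute a ceiling, because no substitution rule is part of the
method. Normalisation makes the statistic scale-invariant, which is tested as
a property.

**Fourier variance ratio.** The normalised segment's periodogram attributes
variance to bins $k = 1..32$ (periods $64/k$ min). The low-frequency band is
periods 8–64 min ($k = 1..8$), the high-frequency band periods 2 to <8 min
($k = 9..32$, Nyquist included). The 8-min bin sits exactly on both printed
band edges; it is assigned to LF so the bands partition the spectrum, and the
Parseval closure (bin variances summing to the series variance, within
$10^{-9}$) is a standing test. No taper or detrending beyond mean removal is
applied — the method specifies none. A pure high-frequency segment leaves
only floating-point dust in LF, so LF below $10^{-12}$ of the total is
treated as an empty band and the ratio flagged undefined.

## Predictors and the discriminant model

Each of the 12 predictors (6 parameters × morning/evening) is regressed on
age and gender, and the residuals are standardised to SD 1 — the
**standardized residual scores** that enter the model, orthogonal to the
covariates by construction. A one-way MANOVA (Wilks' $\Lambda$, Rao's F) is
computed as a screen.

The DFA solves the generalised eigenproblem of between-group against
within-group scatter, $W^{-1}B\,a = \lambda a$, via a Cholesky-symmetrised
eigendecomposition. With $g = 3$ groups there are $\min(g-1, p) = 2$
canonical functions. Derived statistics are pure functions of the
eigenvalues and are verified as identities on every fit:

* canonical correlation $r_i = \sqrt{\lambda_i/(1+\lambda_i)}$,
* explained variance $100\,\lambda_i/\sum\lambda$,
* Wilks' ladder $\Lambda_k = \prod_{i\ge k} (1+\lambda_i)^{-1}$,
* Bartlett's $\chi^2_k = -(N-1-(p+g)/2)\ln\Lambda_k$ with
  $df_k = (p-k+1)(g-k)$ (the textbook multiplier).

Coefficients are scaled so discriminant scores have pooled within-group
variance 1, which makes centroids and the structure matrix (pooled
within-group predictor–score correlations) comparable across software. The
group-size-weighted mean of the centroids is zero on every function.
Loadings below 0.3 in absolute value are masked in the report — at these
sample sizes smaller loadings are uninterpretable — but the full matrix is
always retained.

Classification uses Fisher linear classification functions from the pooled
within-group covariance with priors (proportional to group size by default;
equal priors are a switch, since the original prior setting is not
recoverable and both are needed for sensitivity analysis). Ties break
deterministically to the earlier group in the fixed label order
(bipolar_depression < mania < mixed). Apparent (training-data)
reclassification is cross-checked against an independent linear-discriminant
implementation on dozens of seeded datasets; leave-one-out cross-validation
refits on every $N-1$ subset; the bootstrap resamples cases with replacement
within group, 1000 replicates by default, and reports percentile intervals.

**A note on LOOCV and priors.** On pure-noise predictors, LOOCV with
proportional priors is systematically *below* the prior-implied chance rate
(about 28% against 33% at $N=34$): deleting a case both shrinks its own
group's prior and moves its group mean away from it. With equal priors the
distortion disappears and the null LOOCV accuracy is statistically
indistinguishable from 1/3, which is how the package's null-calibration test
is run. This pessimism is a property of the procedure, worth remembering
when comparing cross-validated to apparent accuracy.

**Known discrepancy.** The published $\chi^2$ values accompanying the
eigenvalues (49.19, 16.36) are not consistent with the textbook Bartlett
multiplier at $N=34$, $p=12$, $g=3$ (which gives a multiplier of 25.5, not
the ~23.5 the printed values imply, suggesting extra predictors entered the
original run). We implement the textbook form and make no attempt to
reverse-engineer the original multiplier; the identity-layer checks use only
quantities derivable from the eigenvalues themselves.

## The synthetic-cohort generator

The generator's job is to produce recordings whose *extracted* features
reproduce the published phase-specific group means — it emulates the study
conditions, not raw accelerometry. Counts within each day-window regime are

$$x_t = \mathrm{round}\!\left(\mu\,e^{b y_t - b^2/2}\right),\qquad
y_t = \sqrt{2 v_{lf}}\sin\!\tfrac{2\pi t}{32} + \sqrt{2 v_{hf}}\sin\!\tfrac{2\pi t}{4} + \sqrt{1-v_{lf}-v_{hf}}\;\mathrm{AR1}(\phi),$$

with random sinusoid phases per regime block and a low-level night regime
(mean 15 counts/min, 45% zero minutes) outside the analysis windows. Each
knob maps near-monotonically to one feature, which makes calibration
tractable:

* $\mu$ → mean counts/min (the lognormal correction $-b^2/2$ keeps the mean
  at $\mu$);
* $b$ → `sd_pct` (lognormal spread);
* $\phi$ → lag-1 autocorrelation; RMSSD then follows automatically via
  $\mathrm{RMSSD} \approx s\sqrt{2(1-\rho_1)}$ — the published RMSSD values
  are consistent with this relation, which is why no separate knob exists;
* $v_{lf}$ (32-min sinusoid share) → lowers sample entropy and the Fourier
  ratio (more regular, more LF variance);
* $v_{hf}$ (4-min sinusoid share) → raises the Fourier ratio.

The six knob sets (3 phases × 2 windows) were calibrated by simulation:
replicate subjects are pushed through the *real* extraction path and each
knob nudged until the Monte-Carlo mean of every feature sits inside the
published 95% CI; the calibrated values are frozen as package defaults. The
standing calibration property (200 replicates per phase, all 36
feature-means inside their CIs) is part of the test suite. Ages are drawn
per phase from normal distributions matching the published group means (SDs
recovered from the CIs), truncated at 18 years; gender is Bernoulli with the
cohort's 56% female fraction; group sizes follow largest-remainder
apportionment of the 12/16/6 cohort fractions.

What the generator does **not** emulate: sleep architecture, naps, device
non-wear (beyond an optional zero-run injection rule used to exercise the
tolerance-relaxation search), medication effects, or between-day
non-stationarity. Passing tests therefore show the pipeline recovers the
*target feature structure*; they cannot show that real recordings satisfy
the generator's distributional assumptions.

## Determinism and numerical choices

* Every stochastic entry point takes a seed; per-subject streams are derived
  from the master seed, so enlarging a cohort or adding knobs never perturbs
  existing subjects. Identical configuration + seed gives bit-identical
  output, tested.
* The eigenproblem is symmetrised through the Cholesky factor of $W$;
  eigenvalues are clipped at 0; fits with $N \le p$ or singular scatter are
  refused with guidance rather than regularised silently.
* Degenerate inputs: constant segments make SD-based parameters undefined
  (error at the single-segment level, exclusion-with-report at the table
  level); all-zero windows escalate the tolerance to 64 and are then
  excluded at the feature stage because their mean is 0.
* Zero-count minutes are exact zeros; no near-zero thresholding.

## Problem sizes used in the shipped checks

The test suite runs the search-vs-brute-force equivalence on 1000 random
series (≤300 min), the sample-entropy oracle on 100 segments, the
discriminant oracle on 50 datasets, the generator calibration at 200
replicates per phase, and the LOOCV null calibration on 500 noise datasets;
the direction-of-effect check on full synthetic cohorts uses 8 replicate
cohorts of 34 subjects with median apparent accuracy required to beat the
largest-group prior (47%). These sizes were chosen so each check's
Monte-Carlo error is small relative to the tolerance it asserts.

## Limitations

* The DFA assumes a common within-group covariance; with $N = 34$ and 12
  predictors the model is close to saturation, which is precisely why the
  leave-one-out estimate matters more than apparent accuracy.
* Calibration targets are model-adjusted group estimates (age- and
  gender-controlled in the source); the generator treats them as plain group
  means, the only option available without raw data.
* The published cross-validated accuracy depends on the original patient
  data and is not reproducible from synthetic cohorts; the package makes no
  claim about it.

## A worked run

```{r, eval = FALSE}
cfg <- pipeline_config(out_dir = "run", n_subjects = 34, seed = 17,
                       n_boot = 1000)
res <- run_pipeline(cfg)
tidy(res$fit)
res$apparent
res$loocv
autoplot(res$fit)
```
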