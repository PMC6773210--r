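---
title: "Modelling ceiling-censored infant looking times with ltcens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling ceiling-censored infant looking times with ltcens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ltcens)
```

## The measurement problem

Preferential-looking experiments with newborns measure how long an infant
fixates a display on each test trial. Two features of these data break the
assumptions of the classical repeated-measures ANOVA that the field
traditionally reports. First, looking times are strongly right-skewed:
multiplicative variation in attentiveness makes a log-normal description far
more natural than a normal one. Second, a trial ends at a fixed ceiling
(60 s here), and a look still in progress at the ceiling is recorded as
exactly 60 s. Such observations are *right-censored*: the true looking time
is known only to exceed the recorded value. Treating them as exact biases
every cell mean downward, most severely in the cells infants like most.

`ltcens` implements, as one reusable and tested pipeline, the full analysis
stack for a bimodal familiarization/test design of this kind:

* the design vocabulary and contrast machinery (13-term single-experiment
  scheme, 21-term cross-experiment aggregate scheme);
* a synthetic-data generator with the design's censoring and two-coder
  measurement structure;
* the classical stack (one-way and mixed ANOVA with partial eta squared,
  Tukey-adjusted marginal-mean comparisons, ML multilevel regression on raw
  and log scales);
* a four-variant Bayesian model family (normal/log-normal likelihood,
  censoring ignored or modelled) with credible intervals, Bayesian
  R-squared, posterior predictive cell intervals, and within-subject
  difference posteriors;
* the aggregate censored log-normal model combining two experiments, with
  derived contrasts;
* simulation-based power analysis.

## The design and its contrast coding

Forty-eight newborns are assigned 16 each to a Congruent, an Incongruent,
and a Shape-Change control condition. After a 60-s familiarization pairing
an auditory number/duration with a visual stimulus, each infant sees two
test trials: a 1-Change trial (auditory change only) and a 2-Change trial
(auditory plus visual change), in counterbalanced order. The design is
therefore Condition (3, between) x First Test (2, between) x Trial Type
(2, within), with familiarization looking time as a subject-level
covariate.

All models are parameterised through one named contrast scheme
(`build_contrast_scheme()`). Coding was chosen so that **every coefficient
equals the cell-mean difference its label names**: two-level factors are
difference-coded (+1/2, -1/2) and the three-level condition factor uses
(2/3, -1/3, -1/3)-type pairs against the Shape-Change control, so e.g. the
"2-Change - 1-Change" coefficient is literally the mean 2-Change minus
1-Change difference. Interaction codes are products of their parents, and
every contrast column sums to zero over the balanced cells. A consequence
worth knowing: the two condition contrasts are *not* orthogonal to each
other (their cell-wise inner product is -1/3); readability of the
coefficients was deliberately preferred over full orthogonality, which only
an orthogonal-polynomial-style coding would give. The full cell-to-code
table can be exported with `scheme_to_json()`.

The aggregate scheme spans five condition-experiment cells (congruent and
incongruent crossed with brightness/length, plus the brightness-only
shape-change control) with nested coding: "Congruent--Incongruent" and
"Brightness--Length" are defined on the four magnitude cells and coded 0 on
shape-change rows; their product carries the condition-by-dimension cell
structure; "Shape Change--Magnitude" is coded (4/5, -1/5) so its
coefficient is the shape-change mean minus the pooled magnitude mean.

The familiarization covariate is centered and divided by its sample SD
(z-score). The applied constants are recorded in the design-matrix
attributes, because a coefficient "per unspecified unit" is not
reproducible otherwise; other scalings are available via
`build_design_matrix(covariate_scale=)`.

## What the generator emulates

`simulate_experiment()` draws, for subject $j$ and trial $i$,

$$\log t_{ij} = x_{ij}^\top\beta + u_j + \varepsilon_{ij},\qquad
u_j \sim \mathrm{N}(0,\sigma_u^2),\quad
\varepsilon_{ij} \sim \mathrm{N}(0,\sigma_e^2),$$

passes the exponentiated latent time through the two-coder measurement rule
and then censors at the 60-s ceiling. Counterbalancing of test order and
familiarization group is exact within condition; each subject has a
deterministic random-number substream keyed by (experiment, condition,
order, slot), so enlarging the design never perturbs existing records.

Default parameters are the package's reference study conditions, fixed once
and derived as follows:

* **`beta`** — the coefficient vector of the censored log-normal fit of the
  reference brightness study (intercept 3.43 log-s, trial-type effect 0.34,
  condition and order interactions as in the reference coefficient table),
  read as labelled cell-mean differences under this package's coding.
* **`sigma_subject` = 0.4, `sigma_obs` = 0.6** — back-derived from the
  reference marginal/conditional pseudo-$R^2$ of roughly 0.29/0.50: with a
  fixed-effects variance near 0.2 on the log scale these ratios imply a
  subject share of about 0.16 and a residual share of about 0.36.
* **`coder_sd_s` = 3.7 s** — two coders disagree by more than the 5-s
  threshold with probability $2\{1-\Phi(5/(\sigma\sqrt2))\}$; a third coder
  was needed on 34% of trials in the reference study, which inverts to
  $\sigma \approx 3.7$ s. The recorded value is the mean of the two closest
  of the (up to three) readings, clamped at the ceiling *after* averaging,
  since online coding is what actually ends a trial.
* **Familiarization looking** is the 60-s familiarization duration times a
  Beta(3, 2.2) attentiveness fraction (mean ~35 s, SD ~12 s), linked to the
  subject intercept through a Gaussian copula with correlation 0.3. The
  reference study only reports that attentiveness "varied widely"; the Beta
  fraction is a modelling convenience that makes that heterogeneity
  explicit and controllable, and the copula correlation is the
  reason familiarization looking is a useful covariate at all.

Under these defaults about 15-20% of trials are censored, matching the
qualitative description of the reference data ("a relatively large number
of observations censored at 60 s").

What the generator does **not** emulate: infant dropout and exclusion,
coder drift or bias (coder noise is unbiased and homoscedastic), trial-level
attention dynamics (habituation within the test phase), and any departure
from log-normality of the latent looking process. Tests that pass on this
generator therefore validate the estimators under the model's own
assumptions — they cannot certify the distributional assumptions against
real infants.

The aggregate generator (`simulate_aggregate()`) adds a length-experiment
block (congruent/incongruent only). Its default cell means reuse the
brightness congruent cells, shift the incongruent length cells down by 0.43
log-units (the reference cross-dimension incongruent offset), and swap the
order-dependence of the incongruent trial-type effect, reflecting the
opposite order pattern reported for the two dimensions. The reference
aggregate coefficient table is printed under a coding whose values are not
recoverable from the available text, so the generator is anchored on this
*derived* (coding-invariant) quantity instead.

## The Bayesian model family

`lt_bayes()` fits the hierarchical model above with either a log-normal or
a normal likelihood, and three censoring treatments:

* `latent` (default): every censored observation is an additional bounded
  parameter constrained above the ceiling and sampled jointly with the
  model parameters. Conditional on those latent values the model is a
  conjugate Gaussian linear mixed model, so the sampler is a
  data-augmentation Gibbs sampler: truncated-normal draws for the latents,
  closed-form multivariate-normal draws for coefficients and subject
  intercepts, and univariate slice updates for the two SDs. The SDs are
  updated from the *collapsed* conditional (subject intercepts integrated
  out analytically per subject), which removes the funnel that makes the
  centered sampler mix poorly when the subject SD is small.
* `integrated`: censored rows contribute the upper-tail probability
  $1-\Phi\{(\log 60 - \mu_{ij})/\sigma_e\}$ directly; the posterior is
  sampled by slice-sampling each scalar parameter (with an interweaved
  non-centered rescaling move for the subject SD). Marginally this is the
  same posterior as `latent`; because the two samplers share no code path
  beyond the priors, their agreement is a genuine end-to-end check, which
  the test suite exercises (coefficient medians within 0.05 log-units).
* `none`: censored values treated as exact, giving the "uncensored"
  variants of the model family.

The latent route is both the faithful formulation (each censored trial gets
its own posterior) and, being fully conjugate, the fast one — a study-size
fit takes on the order of a second — so it is the default; `integrated` is
retained as the independent validation route.

**Priors** (all configurable via `lt_priors()`): coefficients
$\mathrm{N}(0, 1)$ on the log scale ($\mathrm{N}(0, 20\,\mathrm{s})$ raw),
intercept $\mathrm{N}(\log 30, 1)$ ($\mathrm{N}(30, 20)$ raw), SDs
half-normal with scale 1 (20 s raw). On a 0-60 s measurement these are
weakly informative: two prior SDs on the log scale span multiplicative
effects of $e^{2}$, far wider than any plausible looking-time effect, while
still regularising the 8-subject subcells enough to damp small-sample
noise.

**Sampler settings and diagnostics.** Four chains by default; split-R-hat
and effective sample size are computed for every reported parameter, with a
convergence gate (R-hat <= 1.01, ESS >= 400) that attaches a warning —
never silently passes — when unmet. Sampling is deterministic given `seed`.
Summaries are equal-tailed quantile intervals (90% and 95% by default),
with a per-level credibility flag (interval excludes zero); equal-tailed
was chosen over HPD to match standard reporting conventions and to make the
order-statistics oracle in the tests exact.

**Derived posterior quantities.** `bayes_r2()` computes, per draw,
$\mathrm{var}(\eta)/\{\mathrm{var}(\eta)+\sigma_e^2\}$ with the linear
predictor $\eta$ including the subject intercepts, on the model's working
scale — the conditional flavour of R-squared, which is what makes the
log-normal and normal variants comparable on their own scales.
`posterior_predictive_cells()` simulates a new subject and residual per
draw per design cell, clamping at the ceiling when the fitted model
censors. `within_subject_difference()` reports the 2-Change minus 1-Change
posterior per condition-by-order subcondition, on the log scale and as the
difference of implied cell medians in seconds (medians, not means, because
the median is the natural back-transformed location of a log-normal).
`derived_contrast()` evaluates arbitrary weighted combinations of implied
cell means per draw — e.g. the incongruent brightness-minus-length offset
averaging over trial type and order in the aggregate model.

## Classical stack

`mixed_anova()` computes the Condition x First Test x Trial Type
repeated-measures ANOVA through base `aov()` with an
`Error(subject/trial_type)` stratification; partial eta squared uses each
effect's own error stratum. On the 48-subject design both strata have 42
error df. The test suite checks the whole table against a from-first-
principles sums-of-squares oracle (inclusion-exclusion over margin means)
on a mini design.

`marginal_means()` / `tukey_pairwise()` re-implement the marginal-means
machinery: equal-weight cell averaging, with the variance of any cell-mean
combination decomposed over the two strata
($\hat\sigma_s^2 = (MS_B - MS_W)/2$). A combination whose weights cancel
within every subject group is a pure within contrast (within df); one with
constant weights across trial types is a pure between contrast (between
df); genuinely mixed combinations are refused rather than given an
approximate df, since the package deliberately implements no
Satterthwaite/Kenward-Roger machinery. Tukey p-values come from the
studentized-range distribution with the family size actually compared. The
suite cross-checks estimates, SEs, dfs and adjusted p-values against the
`emmeans` package and a Monte-Carlo studentized-range oracle.

`fit_ml_multilevel()` wraps `lme4::lmer(REML = FALSE)` over the package's
design matrix, on raw or log-transformed responses. Coefficient df follow
the containment rule, observations minus subject units (96 - 48 = 48),
which reproduces the df convention of the reference tables; t and p are
computed at that df. Marginal pseudo-R-squared is
$\mathrm{var}(X\hat\beta)$ over the total variance; conditional adds the
subject variance. The term-set ANOVA summary uses Type-III-style Wald F
tests (consistent with sum-to-zero coding), with SS reported on the
residual-mean-square scale so that $SS = F \cdot k \cdot \hat\sigma_e^2$.

## Power analysis

`estimate_power()` is purely simulation-based: datasets from the generator,
the mixed ANOVA on each, and the rejection rate of the named effect at
`alpha`, with its binomial MC-SE. The historical power claim for this
design depended on an unpublished effect size, so the module takes effect
sizes as input (`config$beta`, or multiplicative scalings in
`power_curve()`) and reports curves; it never claims to reproduce any
particular historical figure. Validation: the null interaction rejects at
the nominal 5%, an interaction of three residual SDs saturates, and the
pure trial-type case matches the noncentral-t closed form.

## Numerical choices and degenerate inputs

* Truncated-normal latents are drawn by inversion with the uniform clamped
  below $1-10^{-15}$, which is stable for any censoring fraction occurring
  in this design.
* Slice sampling (stepping-out + shrinkage) is used wherever a conditional
  is non-standard; it is tuning-free, and widths only affect efficiency.
* Coder readings may collide in the closest-pair rule; ties resolve to the
  earlier pair. Recorded times are floored at 1 ms so log transforms are
  always defined.
* A constant familiarization covariate z-scores to a zero column rather
  than dividing by zero; a rank-deficient design matrix is refused.
* `oneway_anova()` flags zero within-group variance (undefined F) rather
  than returning infinity; `mixed_anova()` requires the balanced design it
  claims dfs for.
* ESS uses the multi-chain autocovariance with Geyer's initial monotone
  pair truncation; split-R-hat follows the standard halved-chain form.

## Problem sizes used in the checks

The suite validates at sizes chosen to make Monte-Carlo error negligible
relative to each tolerance: sampler-vs-grid and sampler-vs-sampler checks
run on reduced designs (12-48 trials, the within-factors-only scheme) with
a few thousand draws; interval calibration uses 200 replicates of the full
48-subject design; ML recovery uses 200 replicates at 200 subjects per
condition-order cell; null-power calibration uses 400 simulated
experiments. The calibration and recovery harnesses switch coder noise and
the attentiveness-intercept copula off because they test the estimators
against the model's own generative assumptions; the study-condition
defaults keep both on. The copula matters more than it looks: with
correlation $\rho$ between attentiveness and the subject intercept, the
recoverable familiarization coefficient is $\beta_{fam} + \rho\,\sigma_u$,
not $\beta_{fam}$ — exactly the "attentive babies also look longer at
test" confounding that motivates including the covariate in the first
place.

## Known limitations

* The normal-likelihood variants can place predictive mass below zero
  seconds; they exist for model comparison, mirroring standard practice.
* Because the generator is *exactly* log-normal — subject effects and
  residuals both multiplicative — the raw-scale model's conditional fit on
  synthetic data is statistically indistinguishable from the log-scale
  model's: across replicates the two conditional R² (ML or Bayesian) are
  tied to within noise. On real looking-time data the raw-scale model
  typically fits distinctly worse, but that gap reflects departures from
  exact log-normality (tail behaviour, non-multiplicative heterogeneity)
  that the generator deliberately does not include. A likelihood-ordering
  check on this synthetic data therefore does not discriminate, and the
  suite records this as an expected, documented failure rather than
  asserting the ordering from a favourable seed. What the generator *does*
  robustly reproduce is the censoring direction: ignoring censoring biases
  high-mean cell estimates down and understates their uncertainty.
* Censoring is assumed to occur exactly at a known common ceiling; varying
  or unknown ceilings are out of scope.
* The ML module treats censored values as exact (that is the bridge model
  it reproduces); its recovery guarantees hold for uncensored data only,
  and at study scale its intercept is biased downward on censored data —
  which is precisely the motivation for the censored Bayesian models.
* Subject intercept variance is shared across experiments in the aggregate
  model; nothing in the available description of the reference analysis
  indicates stratified variance components, but the choice is a
  convention, not an inference.
* The coder model assumes independent unbiased coders with a common SD;
  systematic coder bias would be absorbed into cell means and is not
  identifiable from the recorded averages.
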