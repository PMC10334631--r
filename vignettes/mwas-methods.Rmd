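---
title: "Methods: a two-stage medication-wide screen for cancer prognosis on claims data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a two-stage medication-wide screen for cancer prognosis on claims data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mwascreen)
```

## The problem

Hypothesis-driven pharmacoepidemiology asks whether one pre-specified drug
affects one outcome; if only the interesting contrasts get reported, the
literature accumulates selection bias. A medication-wide association study
(MWAS) inverts the workflow: every prescribed drug is screened against the
outcome under a single uniform model, multiplicity is controlled
explicitly, and all results are reported. `mwascreen` implements such a
screen for cancer-prognosis questions on longitudinal health-insurance
claims: the unit of analysis is a cancer patient, the outcome is death
(all-cause or cancer-specific), and the exposures are all non-anticancer
drugs, encoded at two levels of the WHO Anatomical Therapeutic Chemical
(ATC) hierarchy — level 2, the 3-character therapeutic group (`N07`), and
level 4, the 5-character chemical subgroup (`A02AA`).

Because the national claims databases such screens run on are
access-restricted, the package pairs the screen with a synthetic claims
generator whose ground truth (exposure classes, planted hazard ratios,
latent death times) is known exactly. Every statistical guarantee the
pipeline advertises is verified against that ground truth in the test
suite; nothing is asserted about restricted real data.

## Cohort construction

A patient enters the cohort when two conditions hold *jointly*: at least
one diagnosis whose code starts with a configured prefix (default the
colorectal cancer family `C18`, `C19`, `C20`) and at least one qualifying
treatment record (colonoscopy, operation, chemotherapy, radiotherapy).
Diagnosis codes alone are unreliable in claims; requiring treatment
evidence is the standard operational case definition. Time zero is the
earliest qualifying treatment date, and follow-up runs to death or the
administrative end of data coverage (default 2015-12-31), whichever comes
first.

The first two calendar years of coverage (default washout 2 years from
2002-01-01) serve only to verify the absence of prior disease: cases whose
time zero falls inside the washout window are excluded, so the cohort
consists of newly diagnosed patients. The washout keys on the *entry*
(first-treatment) date, not the diagnosis date; the two readings differ
only for patients diagnosed at the washout boundary, and the entry-based
reading is what an entry-date-driven exclusion actually enforces.

Two outcomes are carried per row. The all-cause event fires on any death
inside follow-up. The cancer-specific event additionally requires the
recorded cause of death to be the target cancer; patients dying of other
causes are censored at the death date. This is the cause-specific-hazards
treatment of competing risks, which matches the screening model (a Cox
model per cause); subdistribution (Fine–Gray) hazards are deliberately out
of scope. How raw cause-of-death codes collapse into
`target_cancer`/`other` is an ingestion contract: the dichotomy must be
supplied with the data, because no code list can be derived from the
design itself.

Four covariates adjust every model: sex, age band at entry (15–39, 40–49,
50–59, 60–69, 70–79, >79), Charlson Comorbidity Index band (0, 1–2, 3+)
and the treatment-derived stage proxy. Claims carry no tumor stage;
following the validated practice for this data family, the *pattern* of
cancer treatment stands in for stage: surgery alone marks early disease,
chemo/radiotherapy without surgery marks advanced disease, and
"colonoscopy only" flags patients who received no cancer treatment at all
(terminal presentation). The six categories (colonoscopy only; operation
only; operation + chemo; operation + radio; operation + both;
chemo/radio without operation) are exhaustive and mutually exclusive given
the set of treatment kinds on or after time zero. The attribution window
for that kind set is unbounded by default (time zero to end of coverage)
and configurable. Age enters as the 6-level factor, not continuously: the
screen must apply one uniform adjustment to hundreds of drugs, and the
banded form is robust to the strong age skew of a cancer cohort. The CCI
band is consumed precomputed — the Charlson mapping version and lookback
are data-provider choices the pipeline does not second-guess.

## Exposure: the past-one-year incident-user design

Comparing prevalent users with nonusers is biased: prevalent users have,
by construction, survived on the drug. The classical new-user remedy —
enrol only patients whose use begins after entry — reintroduces
immortal-time and indication problems when entry is a cancer treatment.
The design implemented here defines exposure wholly *before* time zero,
which therefore acts as a landmark: no post-entry information enters the
exposure, so no immortal time can accrue.

Two half-open windows at day resolution partition the lookback
(1 year = 365 days, 1.5 years = 548 days, the ceiling of 547.5; the
windows are configurable):

* **far window** `[t0 − 548 d, t0 − 365 d)` — any prescription here makes
  the patient a *prevalent user* of that drug;
* **near window** `[t0 − 365 d, t0)` — otherwise, any prescription here
  makes them an *incident user*;
* neither — a *nonuser*.

Far-window use takes precedence regardless of near-window use, and
prescriptions on or after `t0` are ignored (a prescription on the entry
day itself is post-entry: exposure is strictly "before study entry").
Prevalent users are *excluded* from that drug's model rather than pooled
with either arm — the contrast of interest is incident users versus
nonusers; an option recodes prevalent to nonuser for sensitivity
analysis. "Nonuser" means no use during the entire 1.5-year lookback;
use older than 1.5 years is invisible to the design, a limitation shared
with any fixed-lookback claims analysis.

Prescriptions are first filtered against an anticancer exclusion list
(a set of ATC prefixes supplied as configuration, since the national
regulatory registry that defines "anticancer" is not itself
reproducible), then truncated to the requested ATC level, and each
patient's dates are pooled per truncated code before classification —
classifying at level 2 is identical to classifying the union of the
level-4 date sets sharing the 3-character prefix. A drug enters the
screen when it has at least `min_users` incident users (default 1; the
analysis scripts use 10 per arm at the model stage, see below).

## The two-stage screen

The cohort is split 1:1 into discovery and validation sets by simple
random sampling (discovery size `floor(ratio·n + 0.5)`, so an even cohort
splits exactly; the split is deterministic given its seed). For each
outcome and each ATC level:

1. every eligible drug (at least `min_users_per_arm` incident users *and*
   nonusers in the split, default 10) is fit in the discovery set with a
   Cox proportional-hazards model: outcome on the binary incident-user
   indicator plus the four adjustment covariates, Efron tie handling by
   default;
2. the raw discovery p values of the converged fits form one
   Benjamini–Hochberg family per outcome × level (matching how such
   screens report one volcano panel per family); drugs with FDR-adjusted
   p ≤ q (default 5%) are the *discovery signals*;
3. discovery signals are refit in the validation set; a signal is
   *validated* when its validation p < 0.05 (two-sided Wald) *and*, by
   default, its effect direction agrees across stages. The
   direction-consistency requirement is configurable because a pure
   p-threshold replication rule is also defensible; consistency is the
   stricter and more interpretable choice.

The BH step-up is implemented directly (order statistics, step-up
threshold `i·q/m`, adjusted value `min(1, min_{j≥i} m·p_(j)/j)`) rather
than delegated, because the multiplicity rule *is* part of the method
under test; the test suite checks it against both an exhaustive oracle
and `stats::p.adjust`. Unconverged or degenerate fits (empty arm,
separation, monotone likelihood) are reported with `converged = FALSE`
but excluded from the family size `m` — they carry no test. The
Benjamini–Yekutieli variant is available by configuration for sensitivity
to dependence; BH is the default since per-drug test statistics across a
screen are approximately independent under the null and BY is
conservative.

Per-drug fits use `survival::coxph.fit` on a precomputed design matrix
(the adjustment block is constant within a split, only the exposure
column and the prevalent-exclusion row subset change per drug), which
makes a 200-drug × 2-outcome × 2-level screen a matter of seconds. A unit
test pins the engine to the `survival::coxph` formula interface to
1e-10.

Volcano output follows the field's convention: x = log2(hazard ratio),
y = −log10(FDR-adjusted p) (raw p for the validation panel, which has no
FDR adjustment), significance boundary-inclusive at y's p ≤ q, p floored
at 1e-300 before the log so that a numerically zero p cannot produce an
infinite coordinate while no realistic value is visibly distorted.

## The synthetic claims generator

The generator emits the same four linked tables a real claims extract
would (patients, diagnoses, treatments, prescriptions) plus the ground
truth behind them. Per patient it draws: sex, age band, CCI band and
treatment category from configurable categorical distributions; an entry
date uniform over 2004–2015; one cancer diagnosis at or up to 30 days
before entry; treatment records realizing the drawn category with the
first treatment on the entry date; and, per drug, an exposure class
(incident with `p_incident`, prevalent with `p_prevalent`, else nonuser)
with prescription dates placed in the corresponding windows (half of the
prevalent users also receive near-window prescriptions, exercising the
classifier's precedence rule). Post-entry prescriptions (10% of patients)
and anticancer prescriptions (10%) are added as noise that the exposure
stage must ignore and exclude, respectively.

Death comes from two independent cause-specific Weibull hazards with a
latent-time minimum — the simplest competing-risk generator whose
cause-specific hazards are exactly proportional, hence exactly the model
the screen fits. Under a hazard multiplier `m`,
`S(t) = exp(−m·(t/λ)^k)`, sampled by inversion. The multiplier is
`exp(covariate log-HRs + Σ planted drug log-HRs over the patient's
incident exposures)`; the planted `log_hr_cancer_specific` scales the
cancer hazard and `log_hr_all_cause` the other-cause hazard, so when the
two are equal the drug's all-cause hazard ratio equals them exactly —
the configuration used by every recovery and power check. Death is
recorded at `t0 + 1 + floor(t)` days (strictly after entry) when inside
coverage; otherwise the patient is administratively censored at the
coverage end, and no event of any kind postdates it.

Default parameters mirror the motivating national-sample colorectal
cancer cohort: 66% male; age mass in the 60s; ~60% CCI 3+; the six
treatment categories at their observed proportions; administrative
censoring at 2015-12-31. The baseline scales (cancer: Weibull shape 0.9,
scale 30,000 d; other: shape 1.0, scale 70,000 d) were calibrated once so
that mean follow-up is ≈ 54 months under those margins — a realism
convenience, not an acceptance claim. The screen-level simulation checks
use a denser-event variant (scales 10,400/36,000 d, ≈ 60% deaths inside
follow-up) so that per-drug fits have the event counts a mortality screen
of a cancer cohort actually sees. Prescription counts per exposed
patient-year (`rx_rate`, default 2) are a free scenario parameter — real
prescription-frequency distributions are not derivable from the design.

What the generator does *not* emulate: confounding by indication (exposure
classes are assigned independently of covariates and prognosis),
non-proportional hazards, informative censoring, dose/duration structure,
and correlated use across drugs. Passing tests therefore demonstrate that
the pipeline's mechanics are correct and its error rates hold *when the
model is true*; they say nothing about bias from indication or
measurement in real claims, which no simulation of this kind can certify.

## Verification surfaces and problem sizes

The test suite checks, at fixed seeds:

* exposure classification against a brute-force window-scan oracle
  (10,000 random instances, exact agreement), plus boundary days 365,
  366, 548, 549 and the entry day explicitly;
* the BH step-up against an exhaustive oracle on 1,000 random p-vectors
  (m ≤ 12, exact rejection sets) and against `p.adjust` on random cases,
  with rejection-set monotonicity in q;
* the simulator round trip: on a 2,000-patient, 50-drug bundle the
  exposure matrix reproduces ground-truth classes on 100% of
  patient × drug pairs;
* parameter recovery: a planted HR of 2 (`p_incident` 0.10, n = 2,000,
  200 replicates) is recovered with mean log-HR within ±0.05 of ln 2 and
  95% CI coverage inside [0.92, 0.98];
* error control: under a global null of 200 drugs (n = 2,000, 100
  replicates) the empirical FDR among discovery rejections stays below
  q + 3 Monte-Carlo SE and validated false signals average ≤ 0.5 per
  replicate — in practice the two-stage rule validates essentially
  nothing under the null;
* power: one HR-2 drug (`p_incident` 0.15) among 199 nulls at n = 4,000
  is discovered *and* validated in ≥ 80% of 100 replicates;
* end-to-end determinism: the full pipeline run twice with identical
  seeds produces byte-identical CSVs;
* structural identities: a 1:1 split of 2,618 patients gives
  1,309/1,309; recoding exposure 1↔0 inverts the hazard ratio exactly;
  validated signals are a subset of discovery signals on every run.

These sizes were chosen as the smallest at which the stochastic checks
are stable across seeds; `scripts/acceptance.R` recomputes the same
quantities from scratch at comparable sizes with a caller-supplied seed.

## Numerical and degenerate-input choices

Dates are ISO-8601 calendar dates; all durations are whole days. Window
membership is half-open, so a single integer day difference decides a
class — there are no ties to break. The discovery-size rounding is
half-up (base R's `round` is banker's and would split 5 patients 2/3
instead of 3/2). A fit is declared unconverged when the engine errors,
the coefficient or its standard error is non-finite, or either exceeds
15 on the log scale (monotone-likelihood separation produces exactly that
signature); such drugs stay in the report with their arm counts but carry
no p value. An empty drug list yields an empty report with a warning, not
an error. Patients younger than 15 at entry fall outside the youngest
band and are dropped with a warning rather than silently binned.

## Known limitations

The screen adjusts for four covariates only; residual confounding by
indication is untouched and is the reason such screens generate
hypotheses rather than causal claims. The stage proxy is coarse and
claims-specific. The validation stage reuses the single 1:1 split — there
is no cross-fitting or meta-analysis across splits. Exposure is a
landmark-time binary; duration, dose and post-entry initiation are out of
scope by design.
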