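---
title: "Validating NEWS and the ROX index for 24-hour ED mortality: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating NEWS and the ROX index for 24-hour ED mortality: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(edscores)
```

## The problem

Emergency departments need a fast first read on which arriving patients
might die within the next day. The National Early Warning Score (NEWS)
aggregates seven parameters into 0–20 points but takes minutes to
collect; the ROX index — oxygen saturation divided by FiO2 divided by
respiratory rate — needs only three and can be repeated at the bedside.
Death within 24 h of arrival is rare (well under 1% in general ED
populations), which is precisely the regime where discrimination (AUC),
calibration and clinical utility (net benefit) can disagree; all three
surfaces are therefore computed side by side.

The registries that hold first-recorded ED vitals at the required scale
are access-restricted, so this package pairs the evaluation machinery
with a synthetic cohort generator that emulates such a population. All
empirical claims in this vignette are the ones the package's test suite
actually computes on generated data.

## The generative model

Each visit carries a latent severity $z \sim N(0,1)$. Death within 24 h
occurs with probability $\operatorname{expit}(\alpha + \beta z)$; the
intercept $\alpha$ is solved by quadrature so the marginal death rate
equals the target prevalence (0.7% by default), and $\beta$
(`severity_effect`, log-odds per SD of severity) defaults to 3.

Every other patient feature depends on $z$ through an interpolation
weight $w(z)$, linear in $z$, scaled so that $E[w \mid \text{died}] = 1$
and $E[w \mid \text{survived}] = 0$ exactly. A vital with configured
survivor mean $m_a$ and non-survivor mean $m_d$ is drawn normal around
$m_a + (m_d - m_a)\,w(z)$ and truncated to physiological bounds
(SpO2 ≤ 100, SBP ∈ [40, 280], RR ∈ [4, 60], temperature ∈ [30, 43] —
bounds are ours, chosen for chart plausibility). This construction makes
the generated stratum means match the configured targets in expectation,
which is what the convergence tests assert — with one caveat: the
configured means are pre-truncation, and for SpO2 (survivor mean 96.7,
SD 3.3, ceiling 100) the clamp shifts the realized mean down by ~0.3.
The tests therefore compare against the closed-form clamped-normal
expectation rather than the raw target.

Two deliberate variance choices:

- The configured SDs are taken from the whole-population column of the
  target registry's descriptive table (its survivor-stratum SBP SD is
  printed inconsistently with the total there; we side with the total).
  The part of each vital's variance that the severity link explains,
  $(m_d - m_a)^2 \operatorname{slope}^2 \operatorname{Var}(z \mid
  \text{alive})$, is subtracted from the configured variance before
  drawing, so the survivor-stratum SD still lands on the configured
  value. A configuration whose SD cannot absorb its stratum separation
  fails loudly rather than clamping.
- Bounded severity-linked probabilities — supplemental oxygen
  (FiO2 > 0.21), alertness (0.96 survivors → 0.30 non-survivors), ICU
  admission (0.02 → 0.50) — use a logistic-in-$z$ link whose two
  parameters are solved by quadrature to hit both stratum expectations
  exactly; an affine weight would clip at 0/1 and bias the strata. These
  targets are only attainable when the severity effect separates the
  strata enough; the default $\beta = 3$ leaves comfortable margin and
  puts the severity score's own AUC near 0.96, so banded vital-sign
  scores land in the high-0.8s/low-0.9s — the regime reported for such
  populations.

FiO2 is a mixture: room air (0.21) unless on supplemental oxygen, in
which case 0.21 + 0.79·Beta(1.2, 3.5) (mean ≈ 0.41). Auxiliaries (urea,
leukocytes) and age interpolate the same way; their stratum targets are
not published in the reference table and were chosen once as clinically
plausible values (urea 6 → 12 mmol/L, leukocytes 9 → 13.5 ×10⁹/L, age
61.2 → 74.1 y). Discharged patients never carry the death flag — the
primary-analysis assumption that nobody discharged from the ED dies
within 24 h is built into the generator, and relaxed only by the
sensitivity analysis. Presentation dates are uniform over 2019-01-01 to
2021-12-31, spanning the 2020-02-01 split.

### Missingness

Per-variable masking rates default to the registry's imputed-value
fractions (respiratory rate 19.7%, temperature 12.4%, FiO2 49.6%,
alertness 68.1%; labs are set at 0.35, a realistic fraction of visits
without bloods). Mechanisms: MCAR masks by independent coin flips; MAR
shifts the masking logit by centred age and disposition (younger,
discharged patients get fewer measurements); MNAR lowers the masking
probability with severity itself — respiratory rate tends to be recorded
only when the patient looks ill. Under MAR/MNAR the marginal rate drifts
slightly from nominal (Jensen), so rate-recovery tests are run under
MCAR. Masking never alters an observed value, and the same seed always
yields byte-identical cohort files.

### What the generator does not emulate

Correlation among vitals exists only through the single latent severity;
real vitals co-vary within severity strata (e.g. fever with
tachycardia). Stratum distributions are truncated normals, without the
heavy tails registries show among non-survivors. Hospitals, triage
categories, seasonality and repeat attendances are absent. Passing tests
demonstrate that the *pipeline* is correct and that the analysis
recovers known generative parameters — not that any particular AUC
value transfers to real patients.

## Scoring

The NEWS chart ships as a versioned YAML asset (`news2012`, the 2012 RCP
bands) rather than hard-coded logic, because the chart is an external
standard the analysis should pin, not own. Values are rounded half-up to
the chart's measurement grid (1 unit; 0.1 °C) before band lookup, and a
sweep test asserts every physiological value lands in exactly one band.
Supplemental oxygen is defined as FiO2 > 0.21 — FiO2 is the only
oxygen-therapy variable in the data model — and scores 2 points; not
alert scores 3. ROX uses half-up rounding at .5, pinned explicitly so a
platform's banker's rounding can never shift an integer score. Scoring
never imputes: a missing input yields a missing score.

## Imputation

Records missing ≥ 4 of the five counted vitals (SBP, heart rate, SpO2,
respiratory rate, temperature) are excluded as unimputable; the rule is
idempotent and logged. The remainder go through chained equations:
initialization from observed marginals, then (by default) 5 sweeps in
each of 20 chains, each incomplete variable regressed on all other
vitals, age, sex, urea, leukocytes, ICU admission *and the outcome*.
Continuous vitals use predictive mean matching with 5 donors and a
Bayesian coefficient draw, so imputed values are always observed donor
values and physiological bounds hold by construction; alertness uses a
logistic draw. Missing FiO2 is PMM-imputed like the rest: there is no
separate oxygen-therapy indicator to gate a room-air default on, and
because the observed FiO2 median is 0.21, donors reproduce the room-air
default empirically anyway. Each chain runs on its own seeded substream,
so chains are exchangeable and the whole object is reproducible.
Downstream estimates are pooled as plain means across sets (the
estimator the pipeline reports), with between/within components and
Rubin's total variance available for interval construction.

## Evaluation

**Discrimination.** AUC is the Mann–Whitney concordance probability with
ties counted ½, after orienting each score (NEWS higher-is-risk, ROX
lower-is-risk). Variance uses DeLong structural components (midrank
implementation, O(n log n)); paired comparisons use the structural-
component covariance and a two-sided normal p. The implementation is
property-tested against exhaustive pairwise concordance at n ≤ 200 and
against an independent implementation (pROC) to machine precision, and
its type-I error is simulation-tested at n = 2000.

**Calibration.** Risk models are univariable logistics of the outcome on
the integer score — the simplest mapping consistent with averaging
"coefficients and intercepts" across imputed sets; a natural-spline
variant (3 df, knots fixed from the pooled score distribution) sits
behind `form = "spline"` for curvature checks. Any intercept-containing
logistic fit makes the mean predicted risk equal observed prevalence
(calibration-in-the-large), asserted to machine precision per imputed
set. Calibration curves group patients per integer score value — the
same x-axis as the observed-mortality-by-score figures — with a
default minimum plotted group size of 20 in pipeline output.

**Decision curves.** Net benefit at threshold $p_t$ is
$TP/N - (FP/N)\,p_t/(1-p_t)$; the exchange rate $p_t/(1-p_t)$ says one
missed death is worth $(1-p_t)/p_t$ false alarms. Standardizing by
prevalence caps the curve at 1. The default grid is 0.001–0.10 in steps
of 0.001: with 0.7% prevalence, clinically relevant thresholds live well
below 10%, and the 3% and 5% landmarks sit inside the grid. Decision
curves are computed per imputed set and averaged (computing them on
pooled predictions instead changes little here, but per-set-then-average
keeps every surface pooled the same way).

## Pipeline choices

- The split date (2020-02-01) belongs to the *post* period: "pre" is
  strictly before the date.
- Subset analyses (pre/post-COVID) refit the risk models within the
  subset, since subset-specific calibration is part of what a split-
  sample validation should show; a flag allows reusing full-cohort
  models.
- The sensitivity analysis flips exactly
  `round(0.0004 × n_discharged)` discharged survivors to deaths, then
  re-imputes from scratch — the outcome is an imputation predictor, so
  re-using the primary imputation would leak the unperturbed outcome.
- Every stage consumes an explicit seed; two runs of `run_study()` with
  the same config serialize to byte-identical JSON.

## Numerical and degenerate-input behaviour

Failure is always explicit: unsolvable prevalence intercepts, stratum
probability targets outside what the severity link can reach, SDs too
small for their stratum separation, 100%-missing variables, single-class
outcomes, complete separation (detected by non-convergence, near-zero
deviance or runaway coefficients), thresholds at 1.0, out-of-range file
values (reported with row and variable). Empty cohorts are legal inputs
to generation and exclusion. Degenerate DeLong comparisons (a score
against itself) return difference 0, p = 1 rather than 0/0.

## Problem sizes in the shipped tests

The suite generates cohorts up to 200,000 patients for
marginal-convergence checks (shared across tests), 20,000–50,000 for
imputation-bias and convergence properties with m = 5 chains, and a few
thousand for end-to-end pipeline determinism with m = 2 — sizes chosen
so the whole suite completes in well under a minute while keeping
Monte-Carlo bands (3 SEs) tight enough to be meaningful. The defaults a
real analysis would use (m = 20, iterations = 5, n in the hundreds of
thousands) remain the package defaults.

## Known limitations

Dead-stratum vital SDs are wider than the survivor stratum by
construction but narrower than registries report; extreme-tail mortality
per score value is correspondingly tamer. The AVPU consciousness scale
is collapsed to a binary alert flag. NEWS2's SpO2 Scale 2, qSOFA and
triage scores are out of scope. The DeLong CI uses the normal
approximation (no bootstrap path). Multilevel (hospital-clustered)
imputation is not modelled, and excluded (≥ 4-missing) records are never
imputed.
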