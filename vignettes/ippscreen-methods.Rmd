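---
title: "Methods: screening, simulation and statistical models in ippscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: screening, simulation and statistical models in ippscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`ippscreen` screens hospital admissions of older patients (70 years and
over) for potentially inappropriate medications (PIMs: drugs present that
are potentially harmful in context) and potential prescribing omissions
(PPOs: indicated drugs that are absent), in the STOPP/START tradition, and
carries the result through prevalence, association and time-trend
analyses. This vignette is the package's account of its models and the
design decisions behind them.

## Unit of analysis and data model

The unit of analysis is a hospital *admission*, not a patient: the same
person admitted twice contributes two rows, and all regression models
treat the patient identifier as a cluster. An admission enters the
analysis when it lasted at least 24 hours, the patient was at least 70
years old at admission, and the stay falls inside the 4-year reference
window (admission on/after its start, discharge strictly before its end).

Five event tables carry the raw data (CSV, UTF-8, ISO-8601 UTC
timestamps): admissions, medication administrations (ATC level-5 code,
timestamp, prescriber specialty), coded diagnoses, laboratory results and
risk scores. Conventions chosen where the source data format leaves room:

* Time intervals are half-open `[start, end)`; "during hospital stay"
  means event time in `[admit, discharge)`.
* Diagnoses use an internal condition-concept vocabulary
  (`concept_vocabulary()`); a shipped ICD-10-prefix table
  (`icd10_to_concept()`) maps registry extracts onto it. This decouples
  the rule catalog from any single coding system.
* The weighted Charlson score uses the original integer weight table
  (1/2/3/6), shipped as `charlson_weights.csv` and overridable.
* The department trajectory is a semicolon-separated sequence in the
  admissions table; analyses only use the distinct count.
* A zero-medication admission is retained: it can still trigger
  condition-based omissions.
* Counts deduplicate: `n_medications` counts distinct ATC level-5 codes,
  `n_diagnoses` distinct concepts. Whether a source system would count
  registry codes or concepts is ambiguous; we count concepts.

## The rule engine

Criteria are declarative YAML documents (`parse_rule_catalog()`), with
drug logic expressed over ATC prefixes, condition logic over concept
groups in conjunctive normal form (each group is a disjunction, all
groups must hold), optional age and laboratory predicates, and one of two
temporal modes.

Medication administrations are point events with precise timing, but
criteria reason about ongoing use. The *exposure window* of a drug class
is `[first administration, last administration + grace]`, with a 24-hour
default grace. Drug-drug criteria (`temporal_mode: overlap`) require
pairwise overlapping windows; drug-condition criteria use
`co_occurrence`, because diagnosis codes are admission-level and carry no
timestamps. Omission (PPO) semantics: the indicated drug has no exposure
window overlapping the *trigger window* — the triggering drug's window
where the rule has drug triggers (a laxative must overlap the opioid
exposure), or the whole stay for condition-triggered rules (an ACE
inhibitor any time during the stay counts).

Laboratory predicates evaluate against the in-stay extreme in the
direction of harm (minimum eGFR, maximum LDL), so any in-stay violation
triggers. A rule referencing an analyte the admission never had measured
evaluates `FALSE` rather than missing — prevalences are percentages of
*all* admissions. The pseudo-concepts `fall_risk` and `delirium_risk`
resolve against the risk-score table (fall-risk flag = 1, DOSS >= 3).
"History or risk of falls" is operationalized as the fall-risk flag OR a
falls diagnosis concept, since screening instruments differ between
hospitals.

The shipped catalog encodes the ten most prevalent criteria (five PIMs,
five PPOs) with explicit ATC operationalizations — e.g. benzodiazepines
`N05BA`/`N03AE`; neuroleptics `N05A` excluding lithium `N05AN`;
antiplatelet `B01AC` overlapping an anticoagulant
(`B01AA`/`B01AE`/`B01AF`) in stable vascular disease; statin omission
requires documented vascular disease *and* LDL > 2.5 mmol/l. These
encodings are the catalog's, are documented in the file itself, and can
be overridden without touching code. The format accepts arbitrarily many
further rules. Dose-based logic and end-of-life exclusions (relevant to
the statin criterion) are out of scope: doses and life expectancy are not
modelled, so the statin omission may over-flag palliative patients.

`screen_cohort()` is a vectorized evaluator (per-prefix exposure windows
are computed for all admissions at once); `evaluate_rule()` is the
reference per-admission path. Their agreement, and agreement with an
independently written nested-conditional oracle, is asserted in the test
suite on thousands of generated admissions.

## The synthetic cohort generator

No patient-level data ship with the package; the generator
(`generate_cohort()`) exists so the full pipeline can be exercised and
validated end to end at study scale. Its defaults
(`default_params_table1()`) *are* the study conditions: 16,687 admissions
from 11,289 patients over four years. Families and calibration:

* **Age**: lower-truncated normal with the latent location/scale solved
  so the *truncated* mean and SD equal 77.2 and 5.76 years at a floor of
  70 (closed-form truncated moments, one-dimensional root find). The
  solved latent location is far below 70, i.e. ages decay from the floor
  — the realistic shape for an "everyone above the cut-off" cohort.
* **Length of stay**: log-normal truncated at 1 day (the inclusion
  minimum), parameters least-squares fitted to the reported quartiles
  2.0 / 4.1 / 8.1 days with the median up-weighted.
* **Medication count**: negative binomial grid-matched to quartiles
  10 / 16 / 24; per-admission targets are materialized as distinct ATC
  level-5 codes. Filler codes come from a fixed pool that deliberately
  avoids every prefix used by the shipped catalog, so filler never
  perturbs criterion flags; counts beyond the pool size (about 50 codes)
  are truncated, which only affects the extreme upper tail.
* **Repeat admissions**: one admission per patient plus a geometric
  number of extras (mean matched to 16,687/11,289 ≈ 1.48 per patient),
  adjusted to the exact totals; readmissions are placed shortly after the
  previous discharge (exponential gap, mean ~20 days), so a patient's age
  stays consistent across admissions without biasing the age
  distribution.
* **Conditions**: chronic concepts are drawn per patient at the reported
  prevalences (hypertension 36.9%, malignancy 32.7%, ..., heart failure
  9.2%); filler diagnoses come from a benign concept pool with no
  Charlson weight and no rule references, Poisson-sized to a median of
  five diagnoses per admission. Vascular-disease concepts needed by three
  criteria are not reported separately in the source summaries; the
  defaults (CAD 20%, cerebrovascular 10%, peripheral arterial 6%) are the
  package's choice of plausible tertiary-hospital rates.
* **Constructed criterion rates**: the drug/condition co-assignments
  behind each shipped rule are constructed, not emergent. For a rule with
  target joint rate rho inside a stratum of probability q (e.g.
  benzodiazepine exposure among fall-risk admissions), the conditional
  assignment probability is rho/q; infeasible combinations (rho > q) are
  a fatal, explained error. All constructed exposures of one admission
  share an anchor timestamp, which guarantees the overlap relations the
  ground truth asserts. The realized assignment is returned as a
  ground-truth table, and engine-vs-construction agreement is asserted at
  100% in the tests — by construction, not estimation.
* **Clustering**: every stochastic channel gets a patient-level normal
  random intercept on the logit scale (SD `sqrt(0.5)` by default). Naive
  intercepts would distort marginal rates (a logit-normal mean is pulled
  toward 1/2), so each channel's location is solved by Gauss-Hermite
  quadrature such that the *marginal* rate equals its target exactly.
* **Calendar trends**: optional per-year log-odds drifts applied to the
  PIM and PPO trigger rates, implemented so the marginal flag rate at
  time t is exactly `plogis(qlogis(rho) + slope * (t - midpoint))` —
  hence a trend model on a single constructed rule recovers `slope` as
  its per-year log-odds.

One published coincidence is honored deliberately: the beta-blocker
omission rate equals the heart-failure prevalence, so with default
parameters *every* heart-failure admission lacks an appropriate
beta-blocker and the C07 filler channel only reaches non-heart-failure
admissions.

What the generator does **not** model: realistic co-prescription networks
beyond the constructed co-assignments, dose information, emergency/day
admissions, inter-hospital variation, death as anything but a Bernoulli
flag, and any drug-condition correlation the construction does not
require. Passing calibration tests therefore shows the pipeline is
correct under the published marginal structure — not that it would
reproduce any particular hospital's joint data distribution.

`generate_association_cohort()` is the lighter harness for model testing:
it draws the covariate table directly (no event materialization) and
binary outcomes from a user-specified logistic model. Outcomes are
calibrated the same way, so the *marginal* probability equals
`plogis(X beta)` exactly and GEE estimates are comparable to the stated
truth without attenuation corrections. An optional case-mix drift raises
count covariates over calendar time, which is how the tests build the
confounded-trend scenario (rising medication/diagnosis burden masking a
falling conditional flag risk).

## Statistical models

**Prevalence** is tabulated as the percentage of all admissions with at
least one PIM/PPO, with strata for exactly 1, 2, 3 and 4-or-more flags
(the strata sum to the at-least-one count by identity) and per-rule
percentages of all admissions, to one decimal.

**Associations** use marginal logistic models fitted by generalized
estimating equations with a robust sandwich variance, clustering on the
patient. No GEE fitter ships with the environment's base stack, so the
package implements one (`fit_gee_logistic()`): Fisher scoring on the GEE
estimating equations, with the exchangeable working correlation estimated
from Pearson-residual cross-products each step and the compound-symmetry
inverse applied in closed form — the whole fit is a few vectorized passes
regardless of cluster count. The working correlation defaults to
exchangeable (repeat admissions of one patient are symmetric);
independence is available and makes the fit collapse to ordinary
logistic ML, which the tests assert to 1e-6 together with agreement of
the robust variance against an independent cluster-loop computation and
against `sandwich::vcovCL`. Non-convergence is reported as a flag with
`NA` estimates; perfect separation and single-class outcomes are errors.

Eight variables are examined: age (per 5 years), gender (female vs
male), number of medications, number of diagnoses, weighted Charlson
score, length of stay (per 5 days), number of departments and number of
prescribing specialties. The two scalings live in one scale map applied
before fitting. Each variable's multivariate model adjusts for its fixed,
DAG-derived confounder set (`adjustment_set()`); the sets are data, not
inference — no graph discovery is attempted. Significance is read at
p < 0.01 (two-sided robust Wald), with no multiplicity correction beyond
that fixed threshold.

**Average predictive comparisons** (`compute_apc()`) translate odds
ratios to the probability scale: the mean predicted probability over all
admissions with the variable set to its observed 75th percentile minus
the same at the 25th (linear-interpolation quantiles, computed on the
full analysis data set — the convention here, since prediction-set
choices differ between implementations); for gender, everyone-female
minus everyone-male. APCs are computed from the adjusted fits.

**Time trends** (`trend_analysis()`) model the flag indicator on
continuous years since the window start — a single per-year odds ratio,
not calendar-year factors — unadjusted and adjusted for the eight
covariates, for the overall outcomes and per top-5 rule. For plotting,
per-admission predicted probabilities are ordered over time with a lowess
(f = 0.3) summary curve.

## Numerical choices and degenerate inputs

* Exposure-window overlap is closed (`start1 <= end2 && start2 <= end1`);
  the 24 h grace is configurable per screening call.
* Quantiles are R type 7 (linear interpolation) throughout.
* The exchangeable correlation estimate is clamped to [0, 0.95]; scoring
  stops at a coefficient step below 1e-8 (max 50 iterations).
* A zero-IQR APC variable yields APC 0 with a warning; a zero time span
  makes trend analysis an error; an empty screening result is a valid
  empty flag table; a zero denominator makes prevalence an error.
* Malformed medication rows (bad ATC syntax, administration outside the
  stay) are rejected row-wise and logged in a validation report; broken
  foreign keys and reversed stay intervals are fatal.

## Problem sizes in the test suite

The calibration and end-to-end checks run at the full 16,687-admission
scale (a few seconds each); engine-oracle equivalence uses 1,000
generated admissions; parameter recovery uses 20,000; the trend scenarios
use 12,000-16,687. Smaller property tests use 200-2,000 admissions. These
sizes are chosen so each check has the statistical resolution its
tolerance implies.

## Worked example

```{r example}
library(ippscreen)

gen <- generate_cohort(default_params_table1(), seed = 42)
co <- apply_inclusion(gen$cohort)
features <- compute_admission_features(co)
flags <- screen_cohort(default_rule_catalog(), co)

prevalence_summary(flags, nrow(features))
association_analysis(flags, features, kind = "PIM")
trend_analysis(flags, features, adjusted = TRUE)$trends
```

Or end to end, writing all tables and the trend figure:

```{r pipeline}
run_pipeline(list(sim_params = default_params_table1(), seed = 42,
                  out_dir = "ipp_output"))
```
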