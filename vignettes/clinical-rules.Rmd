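---
title: "Guideline rules, chart lookup, and validation methodology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Guideline rules, chart lookup, and validation methodology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cvdcds)
library(dplyr)
```

## The problem

Community screening programmes for cardiovascular disease (CVD) in
low-resource primary care shift risk assessment from physicians to
nonphysician health workers. That only works if the assessment logic is
encoded once, correctly, and identically on every device: a patient's
10-year CVD risk category, medication indications, treatment targets,
and referral advice must follow deterministically from the screening
inputs. `cvdcds` implements that logic as a pure rules engine over
tabular patient records, together with the machinery needed to trust
it: a dual-implementation validation harness, a deterministic
rule-boundary test suite, a synthetic cohort generator, and care-cascade
analytics for evaluating what happens after referral.

## Risk model

Risk assessment is categorical, in the WHO/ISH chart tradition: a
complete lookup table maps (sex, diabetes, smoking status, age band,
systolic blood pressure band, total cholesterol band) to one of five
10-year risk bands — below 10%, 10–20%, 20–30%, 30–40%, above 40%.
Two grids are kept: a *high-information* grid indexed by cholesterol
and a *low-information* grid without it. The engine routes each record
automatically: the high-information grid is used exactly when a total
cholesterol measurement is present.

Charts tabulate ages 40–79, so the chart age is clamped:
`impute_chart_age()` maps any adult age into `[40, 79]` (a 25-year-old
is assessed at 40, an 85-year-old at 79). Band edges are half-open
`[lo, hi)` with the outermost bands open to infinity; the defaults are
age `[40,50,60,70,80)`, SBP `(-Inf,140,160,180,Inf)` mm Hg, and total
cholesterol `(-Inf,4,5,6,7,Inf)` mmol/L (values recorded in mg/dL are
converted at 38.67 mg/dL per mmol/L). The band edges travel with the
chart file, so a user transcribing a published chart with different
bands is not tied to these defaults; the defaults are, however,
normative for the bundled fixture and the test-suite.

The chart band is then adjusted by two overrides:

* **Established CVD** — a history of angina/myocardial infarction,
  stroke, or peripheral vascular disease gives category `CVD`
  (`CVD_AND_CHR` if extreme single risk factors are also present).
* **Clinically high risk (CHR)** — without established CVD, any of:
  SBP ≥ 160 mm Hg, DBP ≥ 100 mm Hg, TC ≥ 320 mg/dL, LDL-C ≥ 240 mg/dL,
  or TC/HDL-C ratio strictly > 8.

For ordering purposes (monotonicity checks, risk gates) the adjusted
categories rank `LT10 < R10_20 < R20_30 < R30_40 < GT40 < CHR < CVD <
CVD_AND_CHR`: the override categories are treated as high risk
throughout, and in particular satisfy both the ">20%" and ">30%" gates
in the management rules. This is a design choice the source guidance
leaves implicit; it makes every rule monotone in risk.

## Management rules

Medication indications and targets are disjunctive rule lists; compound
blood-pressure thresholds such as "BP ≥ 160/100 mm Hg" are read as
*either* component exceeding its cut-point. Operators are applied
literally: `≥`-style cut-points are inclusive, `>`-style strict (the
TC/HDL ratio of exactly 8 does **not** trigger; a heart rate of exactly
100 does not).

* **BP-lowering**: established CVD; BP ≥ 160/100; BP ≥ 140/90 and risk
  > 20%; BP ≥ 130/80 and risk > 30%; or extreme lipids.
* **Statin**: established CVD; diabetes; extreme lipids; BP ≥ 160/100;
  risk > 30%; or age ≥ 40 *and* risk > 20% *and* (TC ≥ 200 or LDL-C
  ≥ 120 mg/dL). The age gate uses the raw age, not the imputed chart
  age.
* **Antiplatelet**: established atherosclerotic CVD; extreme lipids;
  BP ≥ 160/100; or risk > 30%.
* **Targets**: BP < 130/80 mm Hg with CVD, diabetes, or extreme lipids,
  otherwise < 140/90. Lipid tiers: TC/LDL/HDL 160/80/45 with CVD,
  180/100/45 with diabetes, 200/120/40 otherwise (HDL is a floor, the
  others ceilings).

Diabetes status is one disjunction — a prior diagnosis, fasting glucose
≥ 126 mg/dL, or random glucose ≥ 200 mg/dL — used identically wherever
"diabetes" appears in the rules.

Risk-underestimation flags (antihypertensive therapy, obesity, family
history of premature CHD/stroke, triglycerides > 180 mg/dL, low HDL-C
< 40/50 mg/dL by sex, fasting dysglycemia, resting heart rate > 100)
mark chart risk as conservative; they inform advice but never change
the category. Two of these the source guidance names without defining,
so the package fixes conventions and exposes them in
`cvd_thresholds()`: obesity is BMI ≥ 27.5 kg/m² (WHO Asian cut-point)
or waist ≥ 90 cm (male) / ≥ 80 cm (female); fasting dysglycemia is a
fasting glucose of 110–125 mg/dL.

Referral is indicated for any adjusted category at or above 20% risk,
any medication indication, or newly detected elevated glucose without a
prior diabetes diagnosis. Smoking-cessation advice follows current
smoking; diet and physical-activity advice follows the obesity flag,
any underestimation flag, or a referral indication. The last rule is
this package's own resolution of an underspecified "any elevated risk
factor" clause; it is deliberately broad, since diet and activity
advice is harmless and cheap.

### Missing data

Optional inputs (waist, the glucose fields, the four lipid fields) may
be absent. The discipline is uniform and explicit: *a rule that needs
an absent value is never triggered by it*, and every derived variable
whose inputs are absent is reported as `NA` ("not evaluable"), never
silently defaulted. Inconsistent handling of missing values is a known
failure mode of hand-coded clinical algorithms, and a uniform rule is
easy to state, test, and replicate in a second implementation.

## The 42 calculated variables

`calculated_variables()` emits a fixed 42-entry registry per record —
banded chart coordinates, derived physiology (BMI, TC/HDL ratio,
TC in mmol/L), classification flags, the chart and adjusted categories,
the three indications, the five targets, and the referral/lifestyle
outputs (`calculated_variable_names()` lists them). The registry is the
unit of validation: two implementations are compared variable by
variable over this schema.

## Validation methodology

The package operationalises dual-programming validation:
`oracle_assess()` is a second, independently coded implementation of
the same plain-language rules — a flat per-record decision table with
literal constants, scanning the chart cell table directly rather than
using the engine's band arithmetic. `compare_cohort()` runs both on a
cohort and reports per-variable agreement; floating-point derivations
(BMI, TC mmol/L, TC/HDL) are compared at an absolute tolerance of
1e-9, everything else exactly, and two `NA`s agree only with each
other.

Agreement claims are only as strong as the inputs, so two input sets
are standard:

* `boundary_suite()` — 161 deterministic records hitting every
  threshold at −1/0/+1 (ratio at 7.9/8.0/8.1), every history-flag
  singleton, every chart band edge, every optional-field missingness
  pattern, and a factorial block mixing moderate BP with age, lipids,
  and smoking so the risk-gated rules fire at varying chart bands.
* a seeded synthetic cohort (1000 records by default).

The harness also supports mutation testing: `compare_cohort()` accepts
an alternative engine, and `cvd_thresholds()` overrides let the test
suite inject single-threshold faults and confirm that each is detected
and confined to the mutated variable's dependency closure.
`export_review_worksheet()` supports the complementary human step: a
seeded sample of cases formatted for independent physician review, with
an engine answer key.

## Synthetic cohorts

`generate_cohort()` draws reproducible screening cohorts from
`cohort_params()`. The defaults emulate a rural Indian community
screening population: 67% female, age 51.4 (SD 13.1) years, SBP 129
(SD 22) mm Hg with a 0.4 mm Hg/year age slope, DBP 80 (SD 12), BMI
24.2 (SD 4.6) kg/m², 13% smokers, and history prevalences of 16%
angina/MI, 1% stroke, 10% PVD, 14% diabetes, 19% on BP-lowering
therapy. Published community profiles rarely include lipid or glucose
marginals, so those defaults are conventions chosen once: lognormal
(right-skewed, as lipid and glucose distributions are), TC around
185 mg/dL, HDL 42/48 mg/dL by sex, triglycerides 140 mg/dL, fasting
glucose 98 mg/dL; lipids jointly present with probability 0.3,
reflecting scarce point-of-care lipid testing. Ages are
truncated-normal on [18, 110]; all values are clipped to the record
domain invariants.

What the generator does *not* emulate: realistic cross-correlations
beyond the SBP–age slope, village-level clustering, measurement error,
or repeat visits. Passing validation on synthetic cohorts therefore
demonstrates that the two implementations of the rules agree and that
the rules behave as specified across the input space — not that field
data will be distributed like the simulation.

## Cascade analytics

`compute_cascade()` counts the screening → referral → definite
BP-medication indication → 1-month attendance → prescription → 3-month
adherence pathway, joining assessments to follow-up records by
participant id (an unmatched follow-up is an error, not a silent
drop). Stage percentages use consecutive-stage denominators and are
rounded half-up to integers, the convention of programme reports;
adherence is expressed against attendance. "At BP target" in
`bp_management_summary()` means strictly below both components of the
patient's engine-assigned target. An `exclude_pvd_only` flag drops
patients whose high-risk classification rests solely on a reported PVD
history (no other CVD history, no CHR factor, chart band below 20%, no
diabetes) — self-reported PVD is unreliable in field use, and this
mirrors the exclusion an evaluation would make.

## Numerical and degenerate-input choices

* Band membership uses half-open intervals; inputs below the lowest SBP
  band edge are clamped into the first band.
* `round_half_up` (floor(x + 0.5)) is used for reported percentages;
  base R's banker's rounding would print 0.5 cases differently.
* Chart files are validated strictly (complete grids, known labels,
  no duplicates — fatal); patient files tolerantly (malformed rows are
  dropped with a warning naming line numbers, since field data entry is
  error-prone).
* `audit_chart_monotonicity()` reports risk inversions along every
  risk-increasing axis step but never fails: a transcribed published
  chart may contain legitimate local inversions.
* The bundled chart (`synthetic_chart()`, also shipped as
  `inst/extdata/synthetic_whoish_chart.csv`) is synthetic and monotone
  by construction — real chart values are not reproduced here; users
  transcribe the published chart for their region into the same file
  format.

## Problem sizes

The test suite validates on the 161-record boundary suite plus
1000-record synthetic cohorts, with marginal-recovery checks at
n = 10,000; these sizes give stable empirical marginals (SE of mean SBP
at n = 1000 is 0.7 mm Hg) while keeping the whole suite fast.

## Known limitations

* The engine covers CVD risk management only: no drug dosing, no
  interaction checking, and elevated glucose leads to referral advice,
  not diabetes management.
* The adjusted-category ordering above `GT40` is a convention; a
  patient with chart band `GT40` who also has an extreme single factor
  reports as `CHR`, which is the intended taxonomy but means the chart
  band is not recoverable from the adjusted category alone (it remains
  in `chart_risk_category`).
* Validation agreement is a property of the two implementations and
  the input distribution, not a clinical-accuracy claim: both
  implementations could share a misreading of the underlying
  guidelines. The physician-review worksheet exists precisely to
  close that loop.
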