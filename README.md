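# cvdcds

A guideline rules engine for 10-year cardiovascular disease (CVD) risk
screening and management in community primary care, with the validation
machinery needed to trust it.

Nonphysician health workers in task-shifted screening programmes rely
on clinical decision support to turn a handful of measurements into a
risk category and a management plan. `cvdcds` implements that
assessment pipeline as pure, tested R functions over tabular patient
records:

* **Categorical risk lookup** against complete WHO/ISH-style chart
  grids — a high-information grid indexed by sex, diabetes, smoking,
  age band, systolic BP band, and total-cholesterol band, and a
  low-information grid used automatically when no cholesterol
  measurement is available. Chart age is clamped into `[40, 79]`.
* **Adjusted classification**: established CVD (angina/MI, stroke,
  PVD) and clinically-high-risk overrides (SBP ≥ 160 mm Hg, DBP ≥ 100,
  TC ≥ 320 mg/dL, LDL-C ≥ 240, TC/HDL > 8) layered over the chart
  band, plus risk-underestimation flags (obesity, low HDL-C, raised
  triglycerides, fasting dysglycemia, resting heart rate > 100, ...).
* **Management rules**: BP-lowering, statin, and antiplatelet
  indications with reason codes; BP targets (< 130/80 mm Hg with CVD,
  diabetes, or extreme lipids, else < 140/90); tiered lipid targets;
  referral and lifestyle advice. Every record yields a canonical
  42-entry calculated-variable registry.
* **Dual-implementation validation**: an independently coded
  decision-table oracle (`oracle_assess()`), per-variable agreement
  reports (`compare_cohort()`), threshold mutation testing, and a
  seeded physician-review worksheet export.
* **Synthetic cohorts**: a reproducible generator calibrated to a rural
  screening population (mean SBP 129 (22) mm Hg, age 51.4 (13.1), 67%
  female, ...) and a deterministic 161-record boundary suite hitting
  every rule threshold at −1/0/+1.
* **Care-cascade analytics**: screened → referred → indicated →
  attended → treated → adherent stage counts and percentages, and
  clinic BP-management summaries.

A synthetic, monotone example chart ships with the package; real
published chart values are deliberately not reproduced and can be
transcribed into the same CSV format (`read_chart()`).

## Worked example

```r
library(cvdcds)

chart  <- read_chart(cvdcds_example("synthetic_whoish_chart.csv"))
cohort <- generate_cohort(500, seed = 42)
out    <- assess_cohort(cohort, chart)

dplyr::count(out, adjusted_risk_category)
#>   adjusted_risk_category     n
#> 1 CHR                       31
#> 2 CVD                      128
#> 3 CVD_AND_CHR               20
#> 4 LT10                     224
#> 5 R10_20                    79
#> 6 R20_30                    16
#> 7 R30_40                     2
```

224 of the 500 synthetic patients sit below 10% 10-year risk; 128 have
established CVD, 20 of those with an extreme single risk factor on top
(`CVD_AND_CHR`), and 31 are clinically high risk on a single factor
alone. Validating the engine against the independently coded oracle on
the same cohort:

```r
compare_cohort(cohort, chart)
#> <cvd_agreement> 500 records, 42/42 variables in full agreement (100%)
```

A single patient's management plan, with the reasons for each
recommendation:

```r
patient_report(out[out$adjusted_risk_category == "CHR", ][1, ])
#> participant_id            : S00001
#> age                       : 37
#> sbp                       : 145
#> dbp                       : 108
#> chart_risk_category       : LT10
#> adjusted_risk_category    : CHR
#> chr_reasons               : DBP>=100
#> bp_med_indicated          : yes
#> bp_med_reasons            : bp_160_100;bp_140_90_risk_gt20;bp_130_80_risk_gt30
#> bp_target_systolic        : 140
#> referral_indicated        : yes
#> ...
```

This 37-year-old's chart band is low (assessed at chart age 40), but a
diastolic pressure of 108 mm Hg makes him clinically high risk, with a
definite BP-medication indication and a referral.

Result objects follow broom/ggplot2 conventions: `tidy()`, `glance()`,
and `autoplot()` work on agreement reports and cascades, and
`plot_risk_mix()` charts a cohort's category distribution.

## Command line

A thin CLI wraps the same functions:

```sh
Rscript inst/cli/cvdcds simulate --out cohort.csv --n 500 --seed 42
Rscript inst/cli/cvdcds assess   --chart chart.csv --in cohort.csv --out assessed.csv
Rscript inst/cli/cvdcds validate --chart chart.csv
Rscript inst/cli/cvdcds cascade  --in assessed.csv --followup fu.csv --out cascade.csv
Rscript inst/cli/cvdcds chart-check --chart chart.csv
```

(after installation, resolve the script with
`system.file("cli", "cvdcds", package = "cvdcds")`).

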