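---
title: "Needs-based behavioral health staffing estimation: model and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Needs-based behavioral health staffing estimation: model and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bhworkforce)
```

## The estimation problem

Community health center grantees report patients, encounters and staffing
annually through the Uniform Data System (UDS), but there is no national
standard for behavioral health staffing, and centers vary widely in
whether and how they staff mental health and substance abuse services
onsite. A needs-based model asks a different question than a
utilization-based one: not *how many providers do centers employ*, but
*how many would be required if every medical patient likely to need care
received it at the observed intensity of care*.

The model chains three steps, each per grantee:

1. **Prevalence → target population.** Medical patients aged 12 and over
   are split into two insurance strata — Medicaid/CHIP/other public plus
   uninsured, versus Medicare plus private — because survey data show the
   first stratum carries roughly double the behavioral health burden,
   while Medicare and privately insured patients have similar rates.
   Stratum-specific past-year prevalence of *mild or moderate* mental
   illness (and, separately, illicit drug or alcohol *abuse*) gives the
   expected number of patients needing treatment.
2. **Target population → visit demand.** Target patients are multiplied
   by the median annual visits per (mental health or substance abuse)
   patient observed across grantees with onsite behavioral health staff.
   Mental health visits are then split across the three provider
   categories by the pooled share of visits each category delivers.
3. **Visit demand → FTE.** Each visit stream is divided by the median
   annual visit load (visits per 1.0 FTE) of its provider category.

Shortage is needed minus existing FTE, floored at zero per grantee and
category. Flooring is substantive, not cosmetic: a center staffed beyond
its estimated need cannot serve another center's patients, so the
national shortage is the sum of per-grantee deficits, and it exceeds the
aggregate needed-minus-existing difference by exactly the excess
capacity at over-served grantees. The package carries that identity
through `aggregate_national()` as `excess_served_*`.

### Exclusions and their rationale

Serious mental illness and substance *dependence* are excluded from the
target populations, on the assumption that those patients are largely
served in specialty safety-net settings and that median visit intensities
observed in primary care would badly understate their needs. The
exclusions are realized entirely through the prevalence inputs — the
rates supplied must cover mild/moderate illness and abuse only — so no
separate severity machinery exists. Patients under 12 and non-medical
(e.g. dental-only) patients are likewise out of scope.

## Parameters that matter

| Parameter | Units | 2010 reference | Role |
|---|---|---|---|
| `median_visits_per_mh_patient` | visits/patient/yr | 3.7 | MH demand intensity |
| `share_licensed` / `share_psychiatrist` / `share_other_staff` | fraction | 0.599 / 0.233 / 0.168 | visit mix |
| `median_visits_per_licensed_fte` | visits/FTE/yr | 889 | licensed provider capacity |
| `median_visits_per_psychiatrist_fte` | visits/FTE/yr | 2,210 | psychiatrist capacity |
| `median_visits_per_other_staff_fte` | visits/FTE/yr | 648 | other-staff capacity |
| `median_visits_per_sa_patient` | visits/patient/yr | 5.8 | SA demand intensity |
| `median_visits_per_sa_fte` | visits/FTE/yr | 1,012 | SA provider capacity |

`reference_parameters_2010()` carries the published 2010 values;
`assemble_parameters()` re-estimates all nine from any cohort, or loads a
literal file so printed-table arithmetic can be reproduced exactly.

Medians, not means, summarize utilization throughout, because UDS
utilization ratios are heavily right-skewed: a few grantees report very
large visits-per-provider or visits-per-patient ratios, and a mean would
let those outliers set the national staffing benchmark. The median
instead equalizes the *typical* observed intensity across centers — a
measure of equity rather than clinical adequacy. No trimming or
winsorizing is applied beyond the median itself; alternative cut-points
can be explored simply by supplying a literal parameter file.

Two eligibility conventions were genuinely open and are resolved as
follows. Visits-per-patient medians require *category-matched* staff:
mental health statistics use grantees with positive mental health FTE
(any of the three categories) and positive mental health patients;
substance abuse statistics analogously. Visit loads are per-grantee
ratios then median — a grantee with zero FTE in a category is excluded
from that category's median, never counted as load zero. For even
cohorts the median is the average of the two middle order statistics.

## Prevalence defaults

The exact survey prevalence values behind the published national analysis
are not printed anywhere, so the package defaults
(`mi_public = 0.17`, `mi_private = 0.08`, `sa_public = 0.024`,
`sa_private = 0.012`) are **back-derived, non-authoritative** values
chosen to blend, at a 76% public/uninsured share, to the national
projection rates of 14.84% (mild/moderate mental illness) and 2.11%
(substance abuse) — i.e. 5.9M and 0.84M target patients out of 40M. They
are config-overridable everywhere (`prevalence_table()`,
`read_prevalence()`), and any serious application should substitute
survey-derived rates.

## The synthetic cohort generator

No grantee-level dataset is distributed with the model, so
`generate_grantees()` produces cohorts with the structure the analysis
assumes, making every downstream stage testable:

* **Sizes** are log-normal (default mean 14,900 medical patients,
  log-scale SD 1.1), chosen so a 1,124-grantee cohort carries roughly
  the 16.8M medical patients of the 2010 program, with the heavy right
  tail characteristic of grantee size distributions.
* **Insurance mix** is Beta-distributed per grantee around a 76%
  public/uninsured mean (concentration 25), and a single configurable
  `frac_age_12plus` (default 0.85) converts total medical patients to
  12-and-over counts — grantee-level age bands are not modeled, and real
  12+ counts can be supplied directly through the CSV interface instead.
* **Onsite behavioral health** is a Bernoulli draw per grantee (default
  rate 0.74). Grantees without onsite staff still carry patients and an
  insurance mix: they enter needs estimation but not utilization
  statistics.
* **Utilization** is generated top-down so ratio medians are
  controllable: encounters are patients × a per-grantee visits-per-patient
  draw (rounded), split across provider categories by a Dirichlet draw
  centered on the target shares, and FTE is encounters ÷ a per-grantee
  visit-load draw. Sampling encounters and FTE independently would leave
  the ratio medians only loosely controlled.

### Exact median calibration

The model's medians are location parameters of log-normal laws, and the
generator controls them through the log-scale location: each standard
normal sample is recentred on its own sample median before
exponentiating, so the *empirical* median of every generated ratio
equals its target exactly (up to integer rounding of encounter counts),
while the draws retain log-normal right skew. This makes median recovery
a sharp property rather than a Monte-Carlo coin flip, and leaves the
dispersion parameters (`ratio_dispersion = 0.5`, `load_dispersion = 0.6`,
size dispersion 1.1) free to govern skew. Pooled visit shares are not
median-based and are recovered statistically; with the default Dirichlet
concentration of 200 a national-size cohort recovers them to ~1–2%.

### What the generator does and does not emulate

It reproduces the marginal structure the model consumes: skewed sizes
and ratios, the insurance mix, the onsite-staffing fraction, and
calibrated utilization medians. It does **not** emulate geographic
clustering (states are assigned uniformly), correlation between grantee
size and staffing model, multi-site organizations, reporting error, or
offsite/paid-referral encounters. Passing tests on synthetic cohorts
therefore demonstrate the *arithmetic and statistical machinery* —
calibration recovery, flooring, aggregation identities — not that the
defaults match any real year's UDS beyond the moments listed above.

## Expansion projection

`expansion_scenario()` scales the program to a projected medical patient
total (default 40 million), splits it by the mean public/uninsured share
and applies prevalence and the utilization parameters. Design choices:

* **Grantee-weighted share.** The mean public share is the unweighted
  mean over grantees of their own 12+ public fraction, reflecting that
  the projection allocates patients center by center; a patient-weighted
  pooled share is available via `mean_public_share(weighted = TRUE)`.
* **Blended rates on the full total.** By default prevalence applies to
  all projected patients with no additional 12+ filter
  (`frac_age_12plus = 1`): the published projection's target of 5.92M
  mental health patients out of 40M equals a blended 14.8% rate applied
  to the full total, so the 12+ restriction is understood as already
  folded into the blended rates. The filter is exposed for scenarios
  that prefer to apply it explicitly.
* **Percent increases** are reported against the 2010 *actuals* (what
  centers really staffed and served), rounded half-up to integer
  percent; a non-positive baseline yields `NA` rather than an error.
* The projection is exactly homogeneous in the patient total, and
  projecting a scenario against its own targets yields zero additional
  need — both are enforced by tests.

## Numerical conventions

All model arithmetic is carried in doubles with no intermediate
rounding; rounding to integers (counts, FTE), one decimal (per-2,500
ratios) and integer percents happens only at reporting. This matters for
reproducing published tables, whose internal sums are consistent with
late rounding. Degenerate inputs fail loudly and specifically: no
eligible grantee for a median, zero pooled encounters, zero visit loads,
zero patient totals and mismatched grantee ids are all named errors, not
NaNs. State tables suppress states with fewer than three grantees (to
avoid indirect identification of individual centers) while always
including them in national totals; unknown state codes group under
`OTHER` with a warning.

## Problem sizes

The test suite and the acceptance script run on cohorts of up to 1,124
grantees — the 2010 national program size (1,012 grantees short of
mental health capacity plus 112 over-served) — which a single core
simulates and analyzes in well under a second; the full
simulate-to-report pipeline on a national-size cohort completes in a few
seconds. These sizes are the study conditions themselves, not a
compromise: the model is linear per grantee and scales trivially.

## Known limitations

* The needs estimates inherit every limitation of median-based
  utilization benchmarks: they encode equity with observed practice, not
  clinical adequacy, and are likely conservative.
* Default prevalence is back-derived (see above), and insurance-stratum
  prevalence from a general-population survey likely understates need in
  the health-center population.
* One reporting year, two insurance strata, no offsite care, no under-12
  patients, no SMI/dependence populations, and no modeling of coverage
  transitions under insurance expansion beyond the single
  public-share assumption.
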