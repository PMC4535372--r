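---
title: "Assessing completeness of primary-care EMR data with emrqual"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing completeness of primary-care EMR data with emrqual}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emrqual)
```

## The problem

Electronic medical records (EMRs) from family practices are an attractive
source of data for research, surveillance and quality measurement — but only
to the extent that physicians actually populate them. A physician who writes
prescriptions on paper, or whose laboratory results arrive as scanned images
rather than through an electronic feed, produces an EMR whose gaps will bias
any secondary analysis that assumes the record is the care.

`emrqual` implements a pragmatic completeness assessment for this setting.
It takes flat relational tables of EMR events — billings, progress notes,
structured blood-pressure/weight measurements, laboratory results,
prescriptions, referrals, consultation letters, and a one-shot snapshot of
the cumulative patient profile (CPP) — and answers three questions:

1. How completely does each physician populate each of fourteen
   documentation fields?
2. How does completeness evolve with *physician* time on the EMR and with
   *patient* time on the EMR?
3. Which physicians fall below a benchmark for a field, suggesting the EMR
   is not being used for that function at all?

## The measures

The atom of the assessment is the **documented visit**: a billing for an
office visit with a progress note by the same physician for the same patient
on the same calendar day. From it the pipeline derives:

- **EMR initiation date** — the earliest day on which a physician's record
  carries at least 10 same-day billing/note pairs. This marks the
  operational (not contractual) start of EMR use. The threshold attaches to
  a single day; a cumulative reading (running total of pairs reaching 10)
  is available as `mode = "cumulative"` for practices that ramped up
  gradually, but the single-day rule is the default because the count
  qualifies the date itself.
- **Active patient** — a rostered patient with at least one documented
  visit in the one-year window under study. Because rostering in this
  setting is exclusive (one physician per patient), activity is judged
  against the rostering physician's own visits.
- **Patient tenure** — time from a patient's first documented visit (any
  physician) to the extraction date, binned `<1`, `1-2`, `2-3`, `>3`
  anniversary years.

Completeness of a field for one physician in a one-year window is a
numerator/denominator pair:

- For the seven event fields, the denominator is the physician's **active**
  patients, and a patient counts toward the numerator when the field is
  populated at least once in the window. Only *structured* laboratory
  results and measurements count: a scanned lab report exists in the chart
  but is invisible to search, decision support and research, which is
  precisely the deficiency being measured.
- Visit documentation is special. Its defining footnote is a per-patient
  proportion, so the canonical numerator counts patients **all** of whose
  in-window office billings carry a same-day note. A per-visit variant
  (documented billings / billed office visits) is also computed
  (`variant = "per_visit"`) since "completion of visit documentation" is
  naturally read either way; both are emitted, and the per-patient one is
  the default. The per-patient reading is strict: with three billed visits
  at a per-visit documentation probability of 0.8, only `0.8^3 = 51%` of
  patients are fully documented.
- For the seven CPP fields, the snapshot is un-timestamped, so the
  denominator is **all** rostered patients and the numerator counts
  non-empty categories at extraction. `cpp_medical_history` is the union of
  the "history of past health" and "problem list" panels, which clinicians
  do not use as distinct fields consistently enough to score separately.

A zero denominator yields an `NA` rate that is excluded from aggregation
and counted in the exclusion log — never imputed as zero, which would
conflate "no eligible patients" with "complete failure to document".

## Time on EMR

Physician-time strata use each physician's own anniversary years:
`[initiation + (k-1)y, initiation + ky)`, half-open at day granularity,
with February 29 anniversaries rolling forward to March 1. Only physicians
whose year-*k* window closes on or before the extraction date enter the
year-*k* stratum, so every contributing physician has a full year of data
and the eligible sets shrink as *k* grows. Patient-time strata all use the
final year before extraction, with event-field denominators confined to
active patients and CPP fields evaluated on all binned rostered patients.
Tenure bins are half-open with exactly-3-years falling in `>3`, so the four
printed labels partition the binned population.

Across physicians, a stratum is summarised by the unweighted mean of
physician-level rates with a normal-approximation interval
`mean ± 1.96·sd/√n`, clamped to `[0, 1]`, degenerating to a point when
`n = 1`. The physician — not the patient — is the unit of analysis: rates
are clustered within practice, and a patient-level binomial interval would
be anti-conservative. A panel-weighted variant is available behind
`weighted = TRUE`.

## Benchmarks

Fields divide into *practice-style independent* fields, where the ideal is
100% completion for every patient, and *practice-style dependent* fields
(labs, prescriptions, referrals, consult letters), where a low rate may
simply be clinical style and only outliers indicate poor EMR use:

| rule | fields | threshold |
|---|---|---|
| `fixed_95` | visit documentation, CPP allergies | 0.95 |
| `fixed_80` | blood pressure, weight, other CPP categories | 0.80 |
| `mean_minus_sd` | labs, prescriptions, referrals, consult letters | `max(0, mean − sd)` |

Three choices the benchmark definition leaves open are made explicit,
logged in the output metadata, and exposed as options: the standard
deviation is the sample (n−1) one, because the observed physicians are a
sample of the practice population; "below benchmark" is a strict
inequality, so a physician exactly at a fixed benchmark meets it; and the
mean−1 SD threshold is computed within the stratum being reported, never
pooled across years, because the distributions are cross-sectional.
`rate_histogram()` bins the physician rates (`[0, w), ..., [1−w, 1]`, top
bin closed) to reproduce the frequency-distribution view on which
benchmarks are drawn.

## The synthetic cohort

No real extracted EMR data can ship with the package, so `simulate_emr()`
generates cohorts with a fully known completeness structure. Each field
follows the schedule

```
p(k) = clamp(p0 + jump·[k ≥ 2] + slope·(k − 1), 0, ceiling)
```

in the physician's *k*-th year on the EMR: a base rate, a distinct
first-to-second-year jump (the period in which field population improves
most), a slower drift, and a ceiling. Visit documentation is generated
per billed visit; every other event field is a per-patient-year Bernoulli
"at least one event", matching the granularity at which the measures are
defined. The CPP snapshot is drawn once at extraction with probabilities
rising in patient tenure — the package's stand-in for profiles filling in
as history accumulates.

The default configuration is the package's study condition set: 40
physicians, mean panel 50, a 7-year extract span with initiation staggered
over the first 2 years (so every physician has at least five full years
and eligibility is strictly nested), 3 office visits per patient-year,
visit documentation scheduled from 0.69 (year 1) to a ceiling of 0.88, and
field/CPP probabilities at levels typical of community primary care
(prescriptions best populated; weights and consult letters worst;
laboratory feeds flat once switched on). Each physician's record begins
with an adoption-day burst of 10 same-day billing/note pairs from 10
distinct patients, giving the initiation-date detector an exact target.
Visit counts are homogeneous Poisson — a configurable stand-in, not a
claim about real visit processes.

What the generator deliberately does **not** emulate: free-text content,
diagnoses and drug names, seasonality, roster churn, inter-physician
heterogeneity in style beyond the shared schedules, and measurement error
in dates. Passing tests on this cohort therefore demonstrate that the
*pipeline* recovers a known structure — not that real EMR data meet any
particular completeness level.

Two knowable artefacts of the design are worth noting when reading
simulated output. First, the adoption-day burst is documented by
construction, so the realized per-visit documentation rate in year 1 sits
a few points above the scheduled 0.69. Second, per-visit rates are
computed on distinct patient-days, so same-day repeat visits collapse;
with ~3 visits/patient-year the effect is negligible.

Randomness is hierarchical: each physician draws from a substream derived
from the master seed, so enlarging the cohort never perturbs existing
physicians' data, and a fixed seed reproduces every table bit for bit.

## Numerical and degenerate-input choices

- All windows are half-open `[start, end)` at day granularity; "one year"
  is an anniversary year, avoiding drift over long spans.
- Dangling foreign keys, duplicate ids, multi-rostering, and events after
  the extraction date are validation errors with row coordinates; patients
  failing the inclusion criteria (no valid insurance, missing birth date)
  are dropped at load with a logged count.
- The initiation-date pair count collapses duplicated billing rows (the
  schema has no billing identifiers, so a duplicated row is literally the
  same record); a day's count is its distinct matched patient-days.
- Physicians without a detectable initiation date are dropped from
  physician-time analysis; every exclusion at any stage is conserved into
  the run metadata.

## Problem sizes used in validation

The test suite validates the pipeline at desk scale, chosen to keep the
estimates' Monte-Carlo error well below the effects being recovered:
oracle-equivalence sweeps over 200 random fixtures of up to 10^3 events;
parameter recovery over 100 replicates of a 40-physician × 50-patient ×
5-year cohort with a known first-to-second-year jump of 0.2; and interval
coverage over 1000 replicates of 50 physician rates. The acceptance script
(`scripts/acceptance.R`) re-runs the default 40-physician cohort end to
end and writes every headline quantity it computes.

## Limitations

The assessment measures *presence*, not correctness: a populated field of
poor quality scores the same as a good one, and nothing here validates
measurement values or note content. De-rostering is not modelled —
rostering is treated as current at extraction. The CPP analysis inherits
the snapshot's lack of timestamps: it can show that profiles of
longer-tenured patients are fuller, but not when they were filled.
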