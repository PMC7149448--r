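---
title: "Methods and design choices in oicera"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design choices in oicera}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(oicera)
```

`oicera` implements a claims-based observational workflow for
opioid-induced constipation (OIC) together with a synthetic claims
generator whose proportional-hazards truth is known. This vignette records
the model, its assumptions, the tunable parameters, and the design
decisions made where the methodology was genuinely open. It states no
empirical result that the package's tests and acceptance script do not
themselves compute.

## 1. The exposure model: drug eras

Pharmacy data give an *issue date* and a *days supply* per fill, plus
per-day inpatient administration records. Two conventions define an era:

* **Supply chaining (stockpiling).** Fills are processed in issue-date
  order; each fill's coverage begins at `max(issue_date, previous coverage
  end + 1)` and runs for `days_supply` days. Supply is shifted, never
  truncated, so total covered days always equal total dispensed days. The
  carryover is unbounded by default (a refill stream can push coverage
  arbitrarily far past the last issue date); a cap was considered and
  rejected because the source algorithm is only approximated in the
  literature and an uncapped rule is the simplest faithful reading.
* **Gap bridging.** Runs of covered days whose internal uncovered gaps are
  all ≤ `gap_days` (default 14) form one era. Day intervals are closed
  (`[start, end]`, both covered) and a gap is `next start − previous end −
  1` uncovered days, so a "fourteen-day gap" means up to 14 permissible
  uncovered days. The brute-force oracle in the tests uses the same
  conventions, painted literally on a day bitmap.

Two open points were resolved as follows. *Inpatient days*: unit
(`days_supply = 1`) administration records enter the same chaining
recurrence as outpatient fills rather than being overlaid as a set union.
When an inpatient day collides with outpatient coverage the union reading
would silently drop a covered day, breaking the conservation property
(covered days = dispensed days) that both the implementation and the
oracle rely on; chaining preserves it. *Bridging across hospitalization*:
the 14-day bridge is applied regardless of hospitalization, because the
inpatient/outpatient distinction in the source concerns the evidence for
coverage, not the gap policy.

The index era is the earliest era that lasts ≥ `min_duration_days` (30),
starts inside the study window, and has no opioid coverage in the
`washout_days` (365) before its start; its first day is the index date
(era day 1). All opioid ingredients are pooled into a single "any opioid"
era group; per-ingredient eras are out of scope.

## 2. Cohort criteria

Applied in a fixed order, each step logged in an attrition report:
any opioid era → qualifying index era → age ≥ 65 at index (completed
years) → continuity of care (≥ 1 encounter in each of `[index−365,
index−1]` and `[index−730, index−366]`) → cancer exclusion (≥ 2 claims
with a cancer code in the pre-index year). Because steps 3–5 are
independent filters, their order affects intermediate counts but never the
final cohort — a property the tests assert via an independent per-patient
predicate oracle.

The cancer *code list* is deliberately a configurable input: the published
exclusion parenthetical is grammatically self-contradictory (the classic
malignancy ranges appear under the word "excluding"), and the original
study defers to a supplementary codeset. The shipped default is a small
synthetic member list from those ranges, matched by exact membership.
"≥ 2 claims" counts claim *records* (two same-day claims count), with a
`distinct_days` toggle.

## 3. Outcome phenotype

A patient is eligible for OIC only while exposed. During the index era the
composite outcome is the earliest of: (a) a constipation diagnosis claim;
(b) a constipation procedure claim; (c) a *new laxative initiation* — a
class-level laxative era starting in the era on era day ≥ 4. Laxative
starts on era days 1–3 are classified preventative (prophylaxis co-started
with the opioid) and are never outcome events. Same-day ties resolve
diagnosis > procedure > medication; no candidate means censoring at era
end, giving `time_days ∈ [1, era length]` by construction.

"New initiation or change in laxative" is operationalized at *drug class*
granularity: a laxative class with no active coverage chains into nothing
and therefore starts a new era, while refills of an already-active class
extend the existing era and never fire the outcome. Channel tabulation
counts any-qualifying-record per channel (the published outcome rows sum
to more than the event union, so channels cannot be exclusive); the
winning channel is reported separately.

## 4. Baseline covariates

All baseline windows are closed, `[index − 365, index − 1]`; the index day
itself is exposure-era territory. Decisions of note:

* **Constipating-medication recency** uses the most recent *chained
  coverage day* before the index: gap 1–30 → `days_30_to_1`, 31–60 →
  `days_60_to_31`, 61–365 → `days_365_to_61`, else none. An era-level
  multi-flag alternative was rejected because its category frequencies
  could exceed 100%, contradicting the published near-partition.
* **Laxative context**: `prevalent` = a laxative era starts before the
  index and covers it; `preventative` = a laxative era starts on era days
  1–3; `prior_not_prevalent` = any prior-year coverage and not prevalent.
* **Pruning**: binary covariates < 1% prevalent are dropped unless on the
  keep list (rare race values, aggregated GI anatomical trauma,
  hyperkalemia, irritable bowel syndrome); labs missing in ≥ 60% are
  dropped; GI-trauma member flags (perforation, rectal prolapse,
  rectocele, megacolon, impaction, anal fissure) are OR-combined first.
  The published tables also list impaction and megacolon as standalone
  rows; the default dictionary carries them only as GI-trauma members to
  avoid duplicated columns.
* Race is one-hot with White (the largest group) as reference; sex is a
  female indicator; age enters in years, untransformed.

## 5. Missing laboratory data

Lab averages are multiply imputed by predictive mean matching: per
incomplete column, least squares on the observed rows, a Bayesian draw of
`(σ², β)`, and for each missing row a uniform draw among the `k = 5`
observed rows with the closest predicted mean, imputing the donor's
*observed* value (support preservation is asserted exactly in tests).
Chained equations cycle `max_iter = 10` times over incomplete columns;
`M = 5` independent imputations. These constants are standard practice —
the source reports none of them — and are all configurable. The survival
outcome is excluded from the default predictor set, matching the stated
predictor list (patient characteristics + other labs); congenial
Nelson–Aalen predictors are a possible extension, off by default.
Per-imputation Cox fits are pooled by Rubin's rules with Barnard–Rubin
degrees of freedom.

## 6. Survival analysis

Cox partial likelihood with **Efron** tie handling (day-granularity data
guarantee heavy ties; Efron is the accepted default), Wald CIs and
p-values, Harrell's C on the fitted linear predictor with a seed-controlled
200-resample bootstrap CI. The solver is delegated to the `survival`
package; product-limit and concordance outputs are verified against
hand-computed oracles on small fixtures. The reporting filter keeps
covariates with `p ≤ 0.05`, HR strictly outside `(0.9, 1.1)`, and CI not
crossing 1 — the indifference-band convention for very large samples —
and is idempotent. Percentages print half-up to two decimals to match
table conventions.

## 7. The synthetic world

`sim_config()` fixes the generator's stated world once:

* **Demographics**: 97.51% male; race White 73.59%, African American
  9.60%, Unknown 14.90%, Asian/Pacific 1.39%, American Indian 0.52%; age
  at index ~ Normal(76, 7.35²) truncated to [65.5, 100].
* **Covariate prevalences**: conditions mirror the published clinical
  characteristics table (hypertension 83.02% … multiple sclerosis 0.23%).
  Drug-class prevalences are *not* published; they were fixed once at
  values realistic for an elderly, heavily comorbid veteran cohort
  (antilipemics 50%, beta blockers 40%, anticoagulants 15%, NSAIDs 15%,
  insulin 12%, antihistamines/genitourinary 10%, quinolones/topical
  analgesics 8%, erythromycins/antigout 5%, antipsychotics 3%, androgens
  1.5%) and never revisited.
* **Effects**: true log-HRs are the logs of the published adjusted hazard
  ratios for the reported covariates; every other covariate has β = 0.
  The two published preventative-laxative × prior-constipation interaction
  rows are represented by a single main-effect flag with β = 0 (interactions
  are out of the default model), and the continuous bicarbonate effect is
  left at 0 because its per-unit scaling is not recoverable from the text.
* **Era lengths**: 50% exactly 30 days, else 30 + Exponential(mean 30)
  days capped at 1024 — chosen to match the published era median 30,
  IQR 30–51, and maximum 1024. Event times are exponential with constant
  daily baseline hazard `h0 = 0.0025`, discretized by ceiling to whole
  days and censored at era end. The published 12.6% prevalence is *not*
  used for calibration (that would be circular); the default world lands
  in the same regime (≈ 10%) as a consequence of the stated choices.
* **Ascertainment**: each true event emits exactly one record, channel
  drawn as diagnosis 0.36 / medication 0.637 / procedure 0.003.
  Medication-channel events on era days 1–3 are pushed to day 4 so the
  generator never manufactures an event the preventative carve-out must
  discard (the carve-out itself is tested with purpose-built fixtures);
  the truth table records the shifted day.
* **Fill noise**: refills chain in ~30-day segments with a 15% chance of a
  1–14-day late gap, a 20% chance of a 1–10-day early (stockpiled) refill,
  and a 5% chance of a 3-day inpatient stay encoded as unit administration
  days. 15% of patients are constructed to fail exactly one inclusion
  criterion; 10% of cohort patients get a second, later era (ignored by
  the first-era rule).
* **Labs**: four tests with MAR missingness (marginal 25–55%, tilted on
  age) and means shifted by kidney disease/diabetes so imputation has
  signal. The ≥ 60% lab-exclusion rule cannot fire under the configured
  world (missingness is capped below 0.6 by contract) and is therefore
  exercised only by fixtures.

Covariates are drawn independently — only marginal prevalences are
published — with a correlation hook reserved in the config. Dates are
integer offsets from 2006-01-01; index dates fall in 2008-01-01 …
2010-11-30.

## 8. What a green test establishes — and what it does not

The generator writes its truth table next to the bundle, but no analysis
stage may read it (the pipeline is tested to be invariant to deleting the
file). Green acceptance tests therefore establish that the pipeline
*recovers a known truth through the full raw-claims encoding*: era
reconstruction, cohort predicates, covariate flags, outcome dates (an
exact bijection), and log-HRs within 3 estimated standard errors at
n = 50,000. They do **not** establish realism of the synthetic world:
covariates are uncorrelated, the baseline hazard is flat, ascertainment is
one record per event, and coding noise/misclassification is absent. Real
headline quantities that depend on the restricted data (outcome
prevalence 12.6%, C-index 0.672, cohort attrition counts) are explicitly
out of scope.

## 9. Known limitations

Dose/strength is ignored throughout (deliberately out of scope).
Proportional-hazards diagnostics, time-varying covariates, and competing
risks are not implemented. The rolling config hash is for manifest
provenance, not cryptographic integrity. At small n (≲ 1,000 cohort
members) very rare covariates can separate in the Cox fit; the fit warns
(`|β| > 10`) and the affected rows are inestimable rather than wrong.
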