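---
title: "Claims cleaning and chlorpromazine-equivalent dose conversion: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Claims cleaning and chlorpromazine-equivalent dose conversion: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cpzequiv)
```

## Why direct dose conversion

Exposure ascertainment for a whole drug class from dispensing claims has to
reconcile many agents, several routes and formulations, and concurrent use.
Consumption-based standardizations (defined daily doses) average over
populations rather than potencies, which makes them a poor basis for drug
*effects* questions.  Direct dose conversion instead expresses every
dispensing as the pharmacologically comparable daily dose of a referent
agent — here milligrams of chlorpromazine per day — via potency-based
equivalence factors, and sums the converted doses per patient.

The catch is that the two claims fields the calculation leans on, the day's
supply and the dispensed quantity, are unreliable in exactly the settings
where conversion matters most (injectables).  This package therefore
couples the conversion with a rule-based cleaning step, and ships a
synthetic claims generator with ground truth so the whole pipeline can be
validated without access to restricted administrative data.

## The cleaning rules

Claims are partitioned by (route, formulation) and each family has its own
repair rule.  All durations are exact day differences; drug matching uses a
canonical token (lower-cased, whitespace-collapsed), so "the same drug"
means the same ingredient regardless of strength.

**Oral and rectal.**  If the next fill of the same drug arrives within
`next_fill_window_days` (default 100, *inclusive*: a gap of exactly 100
days still counts), the recorded day's supply is trusted.  Otherwise it is
replaced by `quantity / oral_fallback_divisor` (default 5).  Five units per
day is the maximum plausible dosing rate for any antipsychotic, so the
fallback can only *lower* the implied daily dose — a deliberately
conservative repair for a field whose true value is unknowable without a
refill to anchor it.  The quotient is rounded half-up to a whole day and
floored at 1 (a day's supply is an integer at least 1; rounding direction
is otherwise immaterial and is documented here for reproducibility).

**Long-acting injectables.**  Each depot drug has a minimum dosing interval
`m` (e.g. 28 days for haloperidol decanoate; the bundled table covers the
bundled catalogue and is user-replaceable).  With `g` the gap in days to
the patient's next long-acting claim of *any* depot drug (depot therapy is
interchangeable for scheduling purposes, unlike oral refills, which are
matched same-drug):

* `days_supply > m` — keep it;
* no subsequent depot claim — set it to `m`;
* `g < m` — set it to `g` (the injection was actually repeated early);
* otherwise — set it to `m`.

The last branch is not forced by the three-branch rule statement the others
come from; setting the supply to the minimum interval is the consistent
completion (the recorded value is implausibly short, and the next injection
is far enough away that `m` is the best available estimate).

**Short-acting injectables.**  The billed costs provide an internal
consistency check: when `|quantity * unit_cost - total_cost| / total_cost`
exceeds `cost_mismatch_tolerance` (default 5%), the quantity is repaired as
`total_cost / unit_cost`, rounded to 2 decimals (a dispensable volume).
The trigger threshold avoids churning rows that disagree only by rounding
noise.  The day's supply then follows the oral rule, with the *repaired*
quantity feeding the fallback division.  Claims with missing costs keep
their quantity.

Cleaning never touches drugs, strengths, dates, costs, or patient
assignment; it is idempotent (a second pass reports zero modifications);
and same-day duplicate claims are kept as distinct claims ("next
prescription" means a strictly later dispense date, since same-day fills
represent concurrent prescriptions).

## Cohort construction

The index date is the first antipsychotic claim inside the accrual window
(defaults 2009-01-01 to 2012-12-31).  A patient whose claims history starts
*before* the window is not a new user; under this index definition such
patients are removed by the washout exclusion, so membership is insensitive
to whether "first claim" is read as first-ever or first-in-window, and the
washout rule does real work.  Exclusions apply in a fixed precedence that
affects only the logged reason, never membership: no dementia; age under
66 completed years at index (66 guarantees a full observable year of
claims history in a plan covering ages 65+); any claim strictly inside
`(index - 365 d, index)`; no claim in `(index, index + 365 d]`.  Follow-up
runs to death or day 365, whichever comes first.

## Exposure assessment

At initiation, only claims dispensed on the index date contribute (a new
user has no earlier supply that could overlap).  At a later timepoint
`t`, a claim contributes when it was dispensed inside the half-open
lookback window `(t - 100 d, t]` *and* its supply covers the timepoint
under the half-open convention `dispense <= t < dispense + days_supply`.
Half-open boundaries on both intervals prevent double counting at the
edges; both are configurable.  The per-claim daily dose is
`strength * quantity / days_supply` — the dispensed drug mass spread evenly
over the supply period — applied uniformly to tablets, short-acting
injections, and depots, which is what makes depot doses commensurable.
Equivalents from all eligible claims are summed regardless of drug or
route.

Each assessment carries two totals, one from raw fields and one from
cleaned fields, with *eligibility re-derived under each field set*.  A
patient counts as "modified by cleaning" when the totals differ by more
than `dose_change_tolerance_mg` (1e-9 mg): the comparison is on the dose,
not the fields, so a field change whose effect cancels does not count.
A patient-timepoint with no cleaned-eligible claims emits no assessment —
off therapy is absent, not zero.  Route strata are oral (rectal folds in),
regular injectable, long-acting injectable, and multiple when more than
one category contributes.  Concurrency counts *distinct drugs*, not
distinct claims: two fills of one drug are one therapy.

Whether "remained on therapy" should instead use a grace-period persistence
definition is a genuinely open operationalization; the coverage definition
above is used because it needs no extra parameter and matches the exposure
eligibility rule exactly.

## The equivalence table

Factors give mg of chlorpromazine-equivalent per mg of drug per day,
anchored at 100 mg/day oral chlorpromazine (risperidone 2 mg ~ 100 mg CPZ,
factor 50; haloperidol 2 mg, factor 50; olanzapine 5 mg, factor 20; ...).
The bundled immediate-release factors are reconstructed from the published
relative-potency equivalence literature; the depot factors are rougher
per-mg-per-day reconstructions.  The bundled table is a working default for
the bundled synthetic catalogue, **not** a validated clinical reference:
for real analyses supply a study-specific table via
`read_equivalence_table()` (CSV or YAML).  The identity entry
(chlorpromazine, immediate, factor 1.0) is enforced at load.

## What the synthetic generator emulates

`simulate_claims()` draws, per patient: an initiating route class (defaults
oral .965, regular injectable .02, multiple .01, long-acting .005 — the
published route distribution for this population rounds to 97/2/1/0.5,
which sums to over 100%, so the oral share absorbs the remainder), an
atypical-vs-typical primary drug (.81 atypical), concurrent therapy at
initiation (overall probability .14; multi-route patients are concurrent by
construction and the extra-drug draw for the others is derated so the
overall rate is exact), refill streams with jittered gaps, geometric
discontinuation per refill (.06, giving roughly 60% persistence at 12
months), constant-hazard mortality (.20 over one year — a realistic figure
for older adults with dementia initiating antipsychotics), and dedicated
small groups of cohort-exclusion violators (underage, washout violators,
single-fill patients, no-dementia patients) so every exclusion rule is
exercised.

Field errors are injected at the index-date claim of a per-patient draw
whose probability depends on the route class (defaults .03/.16/.36/.42 for
oral/regular/long-acting/multiple — the published magnitudes of
cleaning-modified doses per stratum, used here as error rates so the
cleaning step has comparable work to do).  The archetypes are the ones the
rules repair: a day's supply of 1 recorded for a depot injection, a
dispensed quantity of 1 inconsistent with the billed costs, and an
implausibly short oral day's supply (the oral-error patient switches drugs
after the index fill, so the same-drug refill that would otherwise mask the
error never arrives).

Three generator choices are deliberate idealizations, made so that ground
truth is exactly recoverable and the no-error limit is exactly clean:

* dispensed quantities are set at `oral_fallback_divisor` units per day of
  true supply, so the fallback reproduces the true day's supply whenever it
  fires on an error-free claim (in real data quantities are usually one to
  two units per day, and the fallback genuinely — and intentionally —
  deflates the dose of unrefilled fills);
* depot regimens run at exactly the minimum dosing interval, so the
  one-day-injection error is exactly repairable (real inter-injection gaps
  vary, and repair would then be approximate);
* concurrent partner drugs share the primary stream's fill dates, so death
  censoring cannot orphan one stream of a concurrent pair.

Passing the recovery tests therefore shows the *rules are implemented
faithfully and recover errors whose structure matches their assumptions*;
it does not show that real provincial claims would be repaired exactly,
and published real-data results are not reproduction targets here.

## Numerical choices

* Quantiles everywhere are type-7 (linear interpolation), the R default;
  box plots use 1.5 x IQR whiskers truncated to the most extreme data
  point inside the fences.
* Medians of empty strata are absent rows, never zeros.
* Percentages are kept at full precision internally and rounded to one
  decimal only in written output files.
* Dates are day-resolution integers; no month arithmetic is used anywhere
  (the month-6/month-12 timepoints default to days 182 and 365 and are
  configurable).
* Ties and degenerate inputs: a fallback quotient below 0.5 days floors to
  1; duplicate same-day claims are distinct; an empty claim set is a
  contract error for route classification and an absent row elsewhere.
* Validation sizes: the oracle-agreement tests run 50 random cohorts of up
  to 200 patients against independent brute-force re-derivations; the
  recovery test uses a 2,000-patient cohort; share-recovery uses 5,000
  patients with 3-binomial-SE acceptance bands; `scripts/acceptance.R`
  reports a 5,000-patient run.

## Limitations

Dispensed is not consumed: adherence, especially for oral therapy, is not
modelled, so converted doses are upper bounds on ingestion.  Equivalence
factors encode a single mechanism (dopamine antagonism) and carry their own
uncertainty, particularly for depots and newer agents; the bundled defaults
are placeholders to be replaced per study.  The cleaning rules are
jurisdiction-shaped: the 100-day windows, divisor 5, and cost-consistency
trigger all live in `study_config()` precisely because other formularies
will need other values.  The generator's error model covers the three
documented archetypes; real claims contain error modes beyond them.
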