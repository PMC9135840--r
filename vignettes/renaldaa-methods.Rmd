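---
title: "Methods: assessing kidney-function decline under DAA prescription patterns"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: assessing kidney-function decline under DAA prescription patterns}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The question and the design

Direct-acting antivirals (DAAs) against hepatitis C carry heterogeneous
package-insert warnings about kidney disease, and it is unclear whether a
decline in kidney function is a class effect or drug-specific. `renaldaa`
implements a new-user cohort design over electronic-health-record data to
compare the incidence of decreased kidney function across ten DAA
prescription patterns, taking ledipasvir/sofosbuvir (LDV/SOF) as the
control because its insert carries no serious renal warning and it is the
largest interferon/ribavirin-free group.

The real network data this design targets are not publicly accessible, so
the package ships a synthetic-data generator that emulates the statistical
structure the pipeline assumes and injects a known ground truth. Every
empirical claim in this vignette is one the test suite or
`scripts/acceptance.R` computes; nothing is carried over from external
results.

## Data model

Five flat tables — patients, prescriptions (start date and days of
supply), laboratory results (eGFR in mL/min/1.73 m², serum creatinine in
mg/dL), diagnoses and procedures — plus a study window (2009-01-01 to
2017-12-31). Dates are calendar dates with integer-day arithmetic: the
source records carry no time of day, which drives several design choices
below. A patient's `first_record_date` is the minimum date over all four
dated tables, since "having medical records" is not specific to any one
table.

Diagnosis and procedure codes are an abstraction (`diabetes`,
`heart_failure`, `hypertension`, `chronic_kidney_disease`,
`renal_failure`; `renal_dialysis`, `renal_transplantation`): real networks
use local/ICD code systems whose mapping is site-specific, and nothing in
the analysis depends on the coding system. Every `Diagnosis` row is
treated as a confirmed diagnosis; suspected-diagnosis qualifiers are not
modelled.

## Cohort construction

`t0` is the first prescription date of any target DAA inside the study
window. New users must satisfy `first_record_date <= t0 - 90` (the
"90 days or more" of history is boundary-inclusive). Six exclusion
criteria follow, each counted independently so that a patient meeting
several is counted under each (the final cohort removes the union, which
also makes the result order-insensitive):

1. any eGFR below 45 within the 90 days before `t0`;
2. dialysis, transplantation, chronic kidney disease or renal failure
   before `t0`;
3. diabetes, heart failure or hypertension before `t0`;
4. no eGFR and no serum creatinine result within the 90 days before `t0`;
5. multiple distinct DAAs at `t0`, unless the pair is a package-insert
   combination (grazoprevir + elbasvir, daclatasvir + asunaprevir);
6. required concomitant drugs absent within 30 days either side of `t0`.

Two window conventions are applied consistently. "Before `t0`" is strict
(`date < t0`). "Within 90 days before `t0`" is `[t0 - 90, t0 - 1]`: the
index day itself is excluded everywhere, because a `t0` value may have
been measured before or after the first prescription and using it would
invite reverse causation. Criterion 1 uses creatinine-converted values as
well as recorded eGFR — the conversion rule is stated generally, not only
for outcome ascertainment.

Criterion 6 is evaluated through the exposure classification: an entry
whose anchor DAA matches a pattern but lacks the pattern's required
concomitants, or whose single DAA requires a partner product (daclatasvir
without asunaprevir, elbasvir without grazoprevir), is not classifiable
and is counted there. Multi-DAA sets outside the permitted pairs are
counted under criterion 5 only, to keep the two counts distinct.

## Exposure patterns and treatment episodes

The ten patterns pair anchor DAAs with required concomitants (peginterferon
alpha and/or ribavirin), assessed in the closed window `[t0 - 30, t0 + 30]`
on prescription start dates. OBV/PTV/r with versus without ribavirin (P9
vs P8) differ solely by ribavirin presence in that window.

Time at risk is a classical drug era: a prescription covers
`[start, start + days_supply - 1]`; a refill starting at most 28 days
after the current merged supply end extends the era; a single 7-day grace
period is appended at the era end, truncated at the study end. The gap is
measured from the supply end (grace excluded) to the next start —
stitching and extension are deliberately separate, following standard
drug-era conventions. Only the first era from `t0` is analysed.

Asunaprevir and grazoprevir are dispensed only alongside daclatasvir and
elbasvir respectively, and their treatment period is stated to be
"proportional" to the partner's without a definition. We implement
proportionality as identity: the partner drug's era is the episode. An
alternative reading (pro-rating the supply days) would matter only if the
two drugs' refill schedules diverged, which the generator never produces
and real dispensing makes unlikely.

A change of pattern — a prescription of a DAA outside the pattern's anchor
set, after `t0` and inside the episode — censors follow-up on the day
*before* the change: from the change day onwards the exposure is
ambiguous. Censoring on the change day itself was the plausible
alternative; the day-before rule is conservative in never attributing the
change day's risk to the original pattern.

## Outcome and follow-up

Kidney function is staged into the six KDIGO G categories with inclusive
lower bounds (≥ 90, 90 > x ≥ 60, 60 > x ≥ 45, 45 > x ≥ 30, 30 > x ≥ 15,
< 15). Daily values collapse multiple same-day eGFR results by their mean;
serum creatinine is converted only when no recorded eGFR exists that day,
by the Japanese GFR equation

* male: 194 × sCRE^−1.094 × age^−0.287
* female: male value × 0.739

with age in completed years at the laboratory date (the conversion is a
per-measurement operation, so age is not frozen at `t0`). Computed values
are categorised as-is, with no rounding before comparison against the
printed boundaries; recorded values are used as printed.

The baseline is the daily value closest to `t0` within `[t0 - 90, t0 - 1]`.
The primary outcome is the first follow-up day whose category is at least
one worse than baseline (two for the sensitivity definition). Follow-up
runs from `t0` to the first of: the outcome, the treatment-era end, the
day before a pattern change, or the study end; on a tied day the outcome
wins, matching the order in which the four terminating events are listed.
Person-time is `end_date - t0` days divided by 365.25, and exactly zero
when follow-up ends at `t0`. Recovery of kidney function after an event is
out of scope; follow-up simply ends at the event.

## Statistical analysis

Per-pattern incidence rates are events per person-year. The rate ratio
versus the control uses the exact conditional method: given the total
event count, the exposed count is binomial with null probability
`py_e / (py_e + py_c)`; the two-sided p-value and Clopper–Pearson interval
for that proportion (via `stats::binom.test`) are transformed to the
ratio scale. The choice is driven by the small event counts in the rarer
patterns (several below 20 patients), where a log-normal interval is
unreliable; a Wald interval remains available (`method = "wald"`) for
comparison. The original analysis did not name its interval or test, so
the exact method is a defensible stand-in rather than a reproduction.
Significance is flagged at p < 0.01 with raw p-values always reported, and
no multiplicity adjustment is applied (none was applied in the source
analysis). Zero control events yield an infinite-marked estimate with a
finite lower bound; zero person-time yields a not-available rate.

Baseline comparisons per pattern use the Wilcoxon rank-sum test for age
and baseline eGFR and Fisher's exact test for sex, each versus the
control. Tie handling follows `stats::wilcox.test`: exact enumeration for
small tie-free samples, mid-ranks with a continuity-corrected normal
approximation otherwise. Released tables can be passed through
`mask_small_cells()`, which renders counts below 10 as `"< 10"` and
suppresses dependent percentages, mirroring the publication rule of the
source network.

## The synthetic-data generator

`simulate_dataset()` emulates the features the pipeline relies on:

* pattern shares proportional to the published per-pattern cohort sizes,
  plus a 20% non-user background (the tenth pattern defaults to zero
  patients, as observed);
* an elderly, majority-female population (truncated normal age, mean 65,
  SD 10; 57% female) with baseline eGFR from a truncated normal (mean 75,
  SD 12);
* kidney-function tests on an irregular grid averaging 21 days — about
  four tests over a typical 87-day follow-up;
* anchor-drug refills every 28 days over the intended duration (12 weeks;
  24 weeks for daclatasvir + asunaprevir) and the required concomitants
  near `t0`;
* about 20% of kidney labs recorded as serum creatinine, planted by exact
  inversion of the GFR equation so the converted value is known;
* exclusion-criterion carriers at configurable prevalences, each with the
  record that triggers exactly its criterion, and a record anchor exactly
  `history_days` before `t0`.

The event model is a latent exponential time with rate
`event_rate_control × rate_ratio_per_pattern[pattern]`, observable only on
laboratory days: the first test at or after the latent time falls strictly
below the baseline category's lower bound (uniform within the next-worse
category) and stays depressed thereafter, while non-event values are
truncated inside the baseline category so the ground truth is never
ambiguous. This mirrors the interval-censored detection the design
implies — outcomes exist only where a measurement exists. Two consequences
are worth knowing when reading the simulation studies: detection is
delayed to the next test day, and an event latent in the final days of an
era can go undetected, so the estimated rate ratio carries a small upward
bias at realistic test spacing (the control, with the shorter era and the
same grid, loses proportionally more of its late events). The recovery
study's acceptance band is wide enough to contain this by design.

Default event rates are free parameters — the source reports no usable
per-pattern event counts — and 0.5 events per person-year in the control
was chosen once as giving realistic, analyzable counts. The exclusion
prevalences are deliberately far below real comorbidity burdens (the real
flowchart removed ~80% of new users) so a 2,000-patient simulation retains
a usable cohort; the generator emulates structure, not prevalence. It also
makes no attempt at realistic disease progression, correlated
comorbidities or hospital-level clustering, so passing tests say the
pipeline is correct under its stated assumptions — not that those
assumptions hold in any particular network.

Determinism: a single seed drives a per-patient substream
(`patient_seed(seed, i)`), so enlarging a simulation never perturbs
earlier patients' records, and identical configurations produce
byte-identical CSV output.

## Verification and problem sizes

The oracles are independent re-derivations: a log-space evaluation of the
GFR equation (1,000 random triples, agreement to 1e−9 relative error), a
day-coverage drug-era oracle (1,000 random prescription sets), a
day-by-day enumeration of the four follow-up end conditions (500 random
patients, both thresholds), and binomial tail enumeration for the exact
CI and p-value. Fixtures with constructed truth cover the attrition
flowchart (one patient per criterion plus a dual-criterion patient) and a
12-patient set spanning all ten patterns.

The simulation studies use 2,000 patients per replicate: 200 replicates
for recovery of an injected rate ratio of 5 (median estimate within
[4.0, 6.25], exact-CI coverage within [90%, 99%]) and 500 replicates of a
400-patient null population for type-I error (rejection at p < 0.01 at
most 3% of comparisons). These sizes give Monte-Carlo error comfortably
inside the acceptance bands while keeping a full run of the suite in the
minutes range.

## Known limitations

The published cohort counts, baseline table and rate-ratio figure derive
from a non-public database and are not reproducible here; the pipeline
reproduces the *procedure*, exercised on synthetic data. Only the first
treatment era per patient is analysed; covariate adjustment is not
implemented (the design argues restriction makes it unnecessary); and the
diagnosis/procedure vocabulary is an abstraction of site-specific coding
systems.
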