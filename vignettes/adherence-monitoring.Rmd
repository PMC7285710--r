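---
title: "Electronic adherence monitoring: the alarm engine, the four metrics, and the simulated trial"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Electronic adherence monitoring: the alarm engine, the four metrics, and the simulated trial}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adhermon)
library(dplyr)
```

## The problem

Kidney-transplant recipients (KTRs) take immunosuppressants on a strict
twice-daily schedule; non-adherence is a major driver of antibody-mediated
rejection and graft loss. Centralized electronic monitoring systems pair a
smart pill box with a feedback loop: every opening is logged with a
timestamp and pill count, and text-message alarms are sent to the patient
and the medical staff when a dose is missed, mistimed, or wrongly dosed.
This package implements the computational core of such a system — the
alarm engine, the standard adherence metrics, the drug-level variability
summaries, and the arm-wise statistics of a two-arm randomized evaluation —
together with a synthetic cohort generator so the full pipeline runs and is
testable without any patient data.

## The dosing model and the alarm engine

A prescription is a set of fixed clock times (`rx_schedule()`, default
08:00 and 20:00, i.e. a 12-hour target interval) with `pills_per_dose`
pills due at each. An intake is *on time* when it falls within ±`window`
(default 3 h) of the scheduled time.

Matching openings to dose slots is the one place where the engine must
invent policy: pill boxes log openings, not intentions. Each slot, taken
in time order, claims the nearest unclaimed opening within ± half the
target interval (±6 h for twice-daily dosing, which makes assignment
unambiguous); ties in distance go to the earlier record. A matched slot is
then `taken_ok`, `taken_dosage_error` (in-window, wrong pill count) or
`taken_out_of_window`; an unmatched slot is `missed`. Timing takes
precedence over dosage, so a single opening never produces two violation
kinds — one text per violation. Openings claimed by no slot are surfaced
as unscheduled intakes and, by default, generate no feedback: the field's
systems treat "overuse" reporting as a staff-review matter rather than an
automated alarm, and no published rule exists for it.

The alarm chain for a missed dose: the first `missed_dose` message fires
at the *window break* (`scheduled + window`), and while the dose remains
untaken up to `max_escalations` (default 2) further messages follow at
`escalation_gap` (default 30 min) intervals — at most three messages per
violated slot. The chain is anchored at the first alarm ("every 30
minutes" reads most naturally as gaps within the chain, not offsets from
the scheduled time). Any intake matched to the slot stops the chain
instantly: only alarms strictly earlier than the intake are emitted. A
late intake still earns one `timing_error` at the intake instant even when
missed-dose alarms already fired — the violation factually occurred, and
emitting it keeps the feedback stream a complete audit trail. Delivery
latency ("within one hour" in deployed systems) is an operational bound,
not algorithmic content; it is modelled as zero by default and exposed as
`alarm_latency`.

`count_feedback_by_kind(dedupe = TRUE)` counts one missed-dose
*occurrence* per violated slot, the convention under which deployed
systems report per-violation tallies; `dedupe = FALSE` counts raw
messages.

## The four adherence metrics

Over a half-open day range (periods are `[visit_{k-1}, visit_k)` windows
of 28 days, six per 24-week follow-up):

* **Dose-taking adherence** = 100 × pills taken / pills prescribed,
  capped at 100. The formula counts pills irrespective of timing; the cap
  keeps the percentage bounded when unscheduled extras occur.
* **Dose-frequency adherence** = 100 × days of correct daily dosing /
  days. A day is correct iff the number of openings equals the number of
  scheduled doses and every opening carried the prescribed count. Timing
  is deliberately *not* part of this metric — it lives in the next one —
  so the four metrics stay non-redundant.
* **Dose-interval adherence** = 100 × days whose within-day first-to-second
  intake interval lies in `target_interval × (1 ± interval_margin)`
  (9–15 h at the defaults) / days. The denominator is *days*, which is
  only coherent for twice-daily dosing if exactly one candidate interval
  is counted per day; we count the within-day interval, so a perfect
  patient scores 100 rather than 200. This is an interpretive decision —
  the days-denominator definition is internally odd — and the excluded
  overnight (evening→morning) interval is available separately from
  `overnight_intervals()` as a diagnostic.
* **Drug holidays** = 100 × days with no intake at all / days. A missing
  day *is* a holiday: the electronic record is the ground truth and no
  diary imputation is attempted.

Days are calendar dates of the (timezone-naive) local clock;
daylight-saving shifts and travel are out of scope. All four metrics are
invariant under a joint time-shift of events and schedule that crosses no
midnight, monotone in the expected directions as intakes are added, and
are verified exactly against brute-force day-by-day recount oracles in the
test suite.

## Outcome statistics

Within-patient immunosuppressant exposure variability is the classical
`CV% = 100 × SD/mean` of the patient's trough series. The sample (n−1) SD
is used everywhere — a trough series is a sample of typically six visits.
Arm comparisons use the pooled-variance Student t-test (the plain reading
of "independent sample t-test", and the default pooled row of the era's
SAS `PROC TTEST`; Welch is available via `var_equal = FALSE`). Paired
visit-to-visit contrasts use the paired t-test, with the all-zero
difference limit defined as p = 1 and constant non-zero differences
rejected explicitly. Event counts are compared with Pearson chi-squared
(uncorrected) when all expected cells are ≥ 5, otherwise Fisher's exact
test, and the method actually used is always reported alongside the
p-value. Per-patient drug-level outcomes average each patient's six-visit
series (whether published tables use a single visit or the visit average
is typically unstated; the average is the stabler choice and is what
`compare_groups()` documents and does). No multiplicity adjustment is
applied — each outcome is tested at α = 0.05, mirroring standard practice
in these trials — and the written report header says so.

`feedback_subgroup_analysis()` re-runs the same comparison within the
intervention arm, split at ≥ 1 deduplicated feedback occurrence. An empty
subgroup flags its rows `not_computable` rather than erroring, since a
fully adherent arm is a legitimate outcome.

## What the synthetic cohort emulates

Non-adherence is modelled as *unintentional forgetfulness only*: each
slot is independently forgotten with probability `p_miss` (no day-level
autocorrelation — a correlated-lapse model is a non-goal), taken doses are
jittered around the scheduled time (Gaussian, `timing_sd` = 20 min,
truncated to the window), a small late tail (`p_late_tail`) produces
out-of-window intakes, and a small `p_dose_error` produces wrong pill
counts. In the intervention arm each alarm independently rescues a
forgotten dose with probability `p_respond`, with a delay uniform within
the 30-min escalation gap so later escalations remain meaningful. Reminder
alarms cannot address intentional non-adherence, and accordingly no
intentional component exists in the model.

The `"ceiling"` preset is the package default and encodes the study
conditions of a highly adherent KTR cohort: 51 intervention / 54 control
patients, 168 days, and per-slot rates calibrated to the feedback density
such cohorts actually produce — about one missed dose per thousand slots
(`p_miss = 1e-3`), dosage errors at `3.5e-4` and spontaneous out-of-window
intakes at `1.2e-4`. Under it, every per-period arm mean of the four
metrics exceeds 98% (typically 99.7–100%). `p_respond = 0.5` is not
identifiable from published adherence data; it was fixed once at the
midpoint. The `"low_adherence"` preset (`p_miss = 0.2`) is the contrast
scenario in which alarms have real headroom and the intervention arm
separates clearly from control.

Trough levels are Gaussian around a patient-level mean with an adherence
coupling, `level = mean × (1 − coupling × missed_fraction) + noise`,
floored at a small positive value (a log-normal alternative is a
documented possible extension; the Gaussian-with-floor keeps the CV
interpretable). Defaults describe maintenance tacrolimus (5.15 ng/mL,
within-patient SD 1.25 → CV ≈ 24%) and mycophenolic acid (2.7 μg/mL, SD
1.03 → CV ≈ 38%), with between-patient SDs of 1.0 and 1.2. The coupling
coefficient (0.5) is a modelling assumption, not an estimate. Clinical
event flags (de-novo anti-HLA antibodies at 0.10, BK viremia at 0.019)
are arm-independent Bernoulli draws for pipeline testing only; no
clinical-event biology is modelled.

What passing tests on this generator do **not** show: real pill-box data
contain device artefacts (double openings, clock drift, transmission
gaps), behavioural autocorrelation (weekend effects, holidays in the
travel sense), and diary-based control-arm records whose clock-time
fidelity is unknown. The generator reproduces the *statistical structure*
the analysis assumes, which is exactly what makes it a fair test harness
and nothing more.

## Numerical and degenerate-input choices

* Timestamps are timezone-naive local clock times stored on a UTC axis;
  CSV round-trips are exact to the second, simulated stamps are rounded
  to whole minutes.
* Ties (two openings at one timestamp) keep file order; the earlier
  record is matched first.
* The intake window and the 9–15 h interval band are closed intervals; an
  intake exactly at the window break is on time, and an alarm due exactly
  at the intake instant is suppressed.
* Zero-pill rows, malformed timestamps and unknown columns are hard
  errors naming the data line — validation never silently coerces.
* CV requires ≥ 2 levels and a positive mean; `two_sample_t` refuses two
  constant samples; arm comparisons with a constant outcome in both
  groups are flagged `not_computable` instead of erroring, since
  near-ceiling adherence data genuinely produce such cells.
* All randomness flows from explicit seeds; `simulate_cohort()` is
  reproducible bit-for-bit given its master seed, and so is the full
  simulate → feedback → metrics → analyze pipeline.

## Problem sizes used in the checks

The oracle-equivalence checks run 200 random ≤ 14-day logs against
minute-resolution replay and day-recount oracles; parameter recovery uses
200 simulated 28-day patients; t-test calibration uses 500 null
replicates; the ceiling-reproduction check runs 50 seeded replicates of
the full 51/54 × 168-day design. These sizes give Monte-Carlo standard
errors comfortably inside the asserted tolerances.

## A known tension in the ceiling scenario

With alarms that work at all (`p_respond > 0`), the intervention arm's
dose-taking adherence is *genuinely* (if minutely) higher than control —
rescued doses are counted pills. At trial scale this ~0.1 percentage-point
effect is at the edge of detectability, so across the 24 per-period
adherence comparisons a few p-values below 0.05 appear in most simulated
replicates even though every arm mean sits above 99%. A strict
"no significant adherence difference in ≥ 90% of replicates" expectation
is therefore unattainable for any stochastic generator of this structure:
even with identical arms, ~18 informative tests at α = 0.05 leave only
`0.95^18 ≈ 40%` of replicates fully clean. The package reports this
honestly rather than calibrating the generator to hide it; the
corresponding acceptance check documents the expectation and its outcome.

## Limitations

* Box openings are a proxy: neither the hardware nor this model confirms
  ingestion.
* The matching rule is a policy choice; published systems do not specify
  one, and a different rule (e.g. event-major greedy) can classify
  borderline double-openings differently.
* The dose-interval metric's days-denominator reading is one defensible
  interpretation of an internally odd definition, flagged rather than
  asserted as the only reading.
* No pharmacokinetics: the trough coupling is linear and memoryless.
* No message transport, acknowledgement tracking, eGFR computation, or
  satisfaction instruments — the statistical operations behind such
  tables (paired t) are provided, the instruments are not.
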