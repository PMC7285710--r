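# adhermon

Electronic medication-adherence monitoring, end to end: the
reminder-escalation alarm engine of a centralized smart-pill-box system,
the four standard adherence metrics computed from intake-event logs,
intrapatient drug-level variability, and the arm-wise statistics of a
two-arm randomized adherence trial — plus a synthetic cohort generator so
every stage runs without patient data.

## Who this is for

Biostatisticians and trialists working with electronically monitored
dosing data (smart pill boxes, MEMS-style bottles) in populations such as
kidney-transplant recipients on twice-daily immunosuppressants, who need
a tested, reproducible implementation of the monitoring system's
computational core rather than the hardware around it.

## What it computes

**Alarm engine.** Openings are matched to scheduled dose slots (nearest
unclaimed event within ± half the dosing interval). A dose still untaken
at the break of the allowed ±3 h window triggers a `missed_dose` alarm,
with up to two escalations at 30-minute intervals — at most three
messages per violated slot — stopping instantly when an intake arrives.
In-window wrong pill counts yield `dosage_error`, out-of-window intakes
`timing_error`.

**Adherence metrics**, per patient over a period of `D` days with `n`
scheduled doses/day:

- dose-taking adherence = 100 × (pills taken)/(pills prescribed), capped at 100
- dose-frequency adherence = 100 × (days of correct daily dosing)/D
- dose-interval adherence = 100 × (days whose within-day dose interval
  lies in `T(1 ± m)`)/D — 9–15 h for a 12-h interval at a ±25% margin
- drug holidays = 100 × (days with no intake)/D

**Outcome statistics.** Within-patient variability `CV% = 100·SD/mean`
of trough-level series (sample SD); pooled two-sample t, paired t,
Pearson chi-squared with Fisher fallback when an expected cell is < 5;
`compare_groups()` reproduces the row structure of a two-arm transplant
outcome table and `feedback_subgroup_analysis()` the feedback ≥ 1 vs
no-feedback split within the intervention arm. Results are tidy tibbles
with `tidy()`/`glance()` methods and ggplot2 `autoplot()` /
`plot_adherence_by_period()` figures.

**Simulator.** Per-slot Bernoulli forgetting, truncated Gaussian timing
jitter, rare dosage errors and late intakes, probabilistic response to
each escalating alarm in the intervention arm, and adherence-coupled
noisy trough series — with a near-ceiling "ceiling" preset mirroring a
highly adherent 51/54-patient, 24-week trial, and a "low_adherence"
contrast.

## Worked example

```r
library(adhermon)
library(dplyr)

sched <- rx_schedule()
sched
#> <rx_schedule>
#>   dose times      : 08:00, 20:00  (1 pill(s)/dose)
#>   target interval : 12 h, margin ±25% -> allowed 9–15 h
#>   intake window   : ±3 h
#>   alarms          : up to 3 missed-dose messages, 30 min apart

coh <- simulate_cohort(n_intervention = 51, n_control = 54, days = 168, seed = 2024)
adh <- summarize_adherence(coh$events, coh$cohort, sched)
adh |> inner_join(coh$cohort, by = "patient_id") |> group_by(arm) |>
  summarise(across(dose_taking:drug_holidays, mean))
#> # A tibble: 2 × 5
#>   arm          dose_taking dose_frequency dose_interval drug_holidays
#> 1 control             99.9           99.8          99.8             0
#> 2 intervention       100.0           99.9          99.7             0
```

Both simulated arms sit at the >98% adherence ceiling: near-total pill
taking, almost every day fully and correctly dosed, dosing intervals
almost always inside 9–15 h, and no drug-holiday days. The intervention
arm's feedback stream over the 24 weeks:

```r
iv <- filter(coh$events, patient_id %in%
               coh$cohort$patient_id[coh$cohort$arm == "intervention"])
slots <- match_intakes_to_slots(iv, sched,
                                c(as.Date("2024-01-01"), as.Date("2024-01-01") + 168))
count_feedback_by_kind(generate_feedback(slots, sched))
#> # A tibble: 3 × 2
#>   kind             n
#> 1 dosage_error     4
#> 2 missed_dose     30
#> 3 timing_error    26
```

A few tens of alarm occurrences across 51 patients and ~17,000 dose
slots — the sparse feedback regime of a highly adherent cohort (most
timing errors here are alarm-rescued late intakes). The trial comparison:

```r
res <- compare_groups(coh$cohort, adherence = adh,
                      troughs = coh$troughs, clinical = coh$clinical)
tidy(res) |> filter(is.na(period))   # drug-level and clinical-event rows
#>   type       outcome                   mean_1 sd_1  mean_2 sd_2  p_value
#> 1 continuous mycophenolic_acid_cv      43.3   24.1  40.2   26.0  0.525
#> 2 continuous mycophenolic_acid_trough   2.78   1.17  2.78   1.14 0.992
#> 3 continuous tacrolimus_cv             24.1   10.0  26.5   11.0  0.264
#> 4 continuous tacrolimus_trough          5.15   1.27  5.09   1.26 0.807
#> 5 event      bk_viremia                                          0.496
#> 6 event      de_novo_hla                                         0.311

glance(res)
#> # A tibble: 1 × 6
#>     n_1   n_2 n_comparisons n_computable  min_p n_significant
#> 1    51    54            30           22 0.0678             0
```

Tacrolimus troughs near 5.1 ng/mL with ~25% within-patient CV,
mycophenolic acid near 2.8 μg/mL — and, as expected at the adherence
ceiling, no comparison reaches significance: the alarms have no headroom
to improve an already near-perfect cohort.

A thin command-line wrapper over these functions is included at
`inst/cli/adhermon.R` (`simulate`, `validate`, `feedback`, `metrics`,
`analyze` subcommands); preset configurations ship in `inst/extdata/`.

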