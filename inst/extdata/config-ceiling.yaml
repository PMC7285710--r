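# Trial-like near-ceiling adherence scenario: highly adherent twice-daily
# dosing, sparse feedback. All schedule fields at their defaults.
schedule:
  dose_times: ["08:00", "20:00"]
  target_interval: 12
  pills_per_dose: 1
  window: 3
  interval_margin: 0.25
  escalation_gap: 30
  max_escalations: 2
simulation:
  preset: ceiling
  n_intervention: 51
  n_control: 54
  days: 168
analysis:
  var_equal: true
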