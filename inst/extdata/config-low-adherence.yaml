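# Contrasting low-adherence scenario (1 dose in 5 forgotten): alarms have
# real headroom, so the intervention arm separates from the control arm.
schedule:
  dose_times: ["08:00", "20:00"]
  target_interval: 12
simulation:
  preset: low_adherence
  n_intervention: 51
  n_control: 54
  days: 168
analysis:
  var_equal: true
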