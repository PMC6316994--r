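# Example simulation configuration: the 50:50 PLGA preset on a reduced
# mesh, overriding the output schedule. Unset keys fall back to the preset.
preset: plga2
model: smeared
geometry:
  extents_um: [90.0, 90.0, 80.0]
  divisions: [12, 12, 40]
time:
  step_days: 5.0
  n_steps: 15
output:
  keep_fields: no
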