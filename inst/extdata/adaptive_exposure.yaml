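# Adaptive exposure preset: two fields of view of dye-stained cells whose
# red signal decays (half-life ~2.8 h); the controller holds the measured
# mean fluorescence at 3000 a.u. by constant-step exposure adjustment.
scenario: adaptive_exposure
seed: 1
frames: 60
positions: [pos1, pos2]
periods: {brightfield_min: 3, fluorescence_min: 3}
channels:
  fluorescence: [RFP]
sample:
  n_cells: 50
  dye_half_life_min: 170
  dye0: 29.5
  growth_rate_per_min: 0.002
control:
  target: 3000
  deadband: 150
  step_ms: 5
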