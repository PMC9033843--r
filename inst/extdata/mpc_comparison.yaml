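# MPC strategy comparison preset. The reporter here is a destabilised,
# fast-turnover variant (half-life 30 min) so that a 30-step (3 h)
# experiment contains a genuine regulation phase; see the methods vignette.
scenario: mpc_comparison
seed: 1
model:
  k: 0.6
  gamma: 0.023105   # ln(2)/30 per min
control:
  target_fluor: 1500
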