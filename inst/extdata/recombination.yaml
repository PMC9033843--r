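# Recombination patterning preset: ring-region targeting with eroded-mask
# DMD stimulation (1 s every 6 min) and endpoint phenotype classification.
scenario: recombination
seed: 1
frames: 60
sample:
  n_cells: 25
  image_shape: [320, 320]
targeting:
  mode: ring
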