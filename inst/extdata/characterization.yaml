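# Characterisation preset: three cell groups under distinct binary light
# profiles (6-min steps, 1000 ms pulses); the deterministic delayed model
# is refitted with the maturation delay profiled on a 3-min grid.
scenario: characterization
seed: 1
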