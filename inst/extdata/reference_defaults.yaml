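# Frozen reference analysis settings; pipelineConfig() defaults must match.
resolution: 4.0
min_male_nuclei: 100
pseudocount: 1.0e-256
target_sum: 10000.0
offset: 1.0e-9
test_mode: unpaired
orientation: female
replicates_per_sex: 6
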