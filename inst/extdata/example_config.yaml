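# Example run configuration: information-integration task, fixed 500 ms
# feedback delay, 5 blocks of 80 trials, 50 replications.
stimuli:
  task: II
experiment:
  delay_ms: 500
  n_blocks: 5
  trials_per_block: 80
  n_replications: 50
master_seed: 1
output_dir: results
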