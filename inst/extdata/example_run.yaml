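# Example eegram run configuration (see ?default_run_config for all keys).
task: burst_eeg
n_samples: 500
n_classes: 2
channels: 22
timepoints: 1000
glimpse:
  k: 3
  base_rows: 6
  base_cols: 60
  scale_factor: 2
  pad_value: 0
T_steps: 6
sigma: 0.17
gamma: 1
lr: 0.003
epochs: 30
batch_size: 32
seed: 1
split: none
out_dir: runs/burst_demo
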