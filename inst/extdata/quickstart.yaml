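# 12-class synthetic SSVEP set decoded with eTRCA: the smallest complete run.
seed: 7
data:
  synth:
    n_classes: 12
    n_channels: 8
    n_trials_per_class: 6
    fs: 250
    trial_len: 0.5
    snr_db: 10
method:
  type: etrca
  n_bands: 3
evaluation:
  selection_time_overhead: 0.5
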