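# Desk-scale demo configuration for `erptfpca run-all`:
# 12 subjects, 64 trials, reduced montage and rates.
seed: 7
generator:
  n_subjects: 12
  n_trials: 64
  sampling_rate: 128
  n_eeg: 8
  n_eog: 1
preprocessing:
  min_epochs: 5
timefreq:
  downsample_to: 64
  n_freq_bins: 33
stats:
  between: [reexperiencing, audit_c]
  robust: true
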