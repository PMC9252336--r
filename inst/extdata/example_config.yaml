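# Example experiment configuration: PD vs HC on a synthetic cohort with the
# study's group sizes. Unset keys take the package defaults.
task: pd_vs_hc
seed: 7
cohort:
  source: synthetic
  effect_size: 1.0
preprocessing:
  smote_k: 5
  test_fraction: 0.3
training:
  max_epochs: 25
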