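# Example pipeline configuration for load_run_config(); the simulate block
# maps onto sim_config() fields, the rest onto run_pipeline() options.
simulate:
  n_physicians: 1000
  seed: 42
  target_adoption_rate: 0.25
  true_gamma: {P: 0.6, G: 0.0, H: 0.3, T: 0.0}
min_shared: 1
year_window: 1
adoption_rule: median
min_per_quarter: 1
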