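# Example experiment scenario for read_scenario().
# Keys mirror the arguments of experiment_config(); `drift` maps to
# drift_spec() and `seed` is returned alongside the config.
seed: 42
n_species: 3
prevalence: 0.03
shape: [60, 60]
n_modern: 150
hist_frac: 0.5
variable_sets: [apriori3]
procedures: [bioclim, domain, glm, kde, maxent_surrogate]
reps: 10
train_frac: 0.7
evaluate: false
drift:
  temp_offset: 1.0
  prec_offset: -3.0
  noise_sd_temp: 0.3
  noise_sd_prec: 2.0
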