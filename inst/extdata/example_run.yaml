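# Example pipeline configuration: a small synthetic two-region study.
simulate:
  n_regions: 2
  plots_per_region: 30
  n_species_pool: 200
  scales: [500, 1000, 2000]
filters:
  min_species_level: 0.5
  min_total: 0.8
  min_plots: 5
causal:
  traits: [wood_density, seed_mass]
  statistics: [cwm, p05, p95]
  exposures: [forest_loss, n_patches, edge_density, degradation]
  spatial_filter: false
niche:
  n_iter: 1000
dcca:
  n_perm: 199
alpha: 0.05
seed: 1
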