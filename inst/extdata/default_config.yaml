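# Shipped run configuration for the synthetic end-to-end pipeline.
# Sizes are chosen so the full run completes in well under a minute while
# every downstream stage still has planted structure to recover.
seed: 1

simulate:
  n_genes: 4000
  cells_per_stage: {W07: 120, W09: 120, W11: 120, W17: 120}
  depth_mean: {epithelial: 25000, immune: 5000}
  stem_fraction: 0.15
  cancer_scope: stem
  cancer_fraction_by_stage: {W07: 0.10, W09: 0.30, W11: 0.60, W17: 0.90}
  # strong enough for median-split recovery, gentle enough that normal and
  # cancer stem-like cells co-cluster (one mixed stem cluster)
  signature_effect: 4
  n_sig_up: 60
  n_sig_down: 40
  nb_dispersion: 0.3

preprocess:
  scale_factor: 10000
  n_hvgs: 3000
  n_pcs: 30
  resolution: 0.4
  k_neighbors: 20

bulk:
  n_per_group: 3
  fold_change: 4
  dispersion: 0.05

gates: {max_fdr: 0.05, min_fc_up: 1.5, max_fc_down: 0.67}

cohort: {n_subjects: 200, hazard_ratio: 3, censor_rate: 0.2}

crosstalk: {min_fraction: 0.1, min_z: 1}
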