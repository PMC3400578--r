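# featherkit demo pipeline configuration.
# Any key omitted here falls back to the documented default; unknown keys are
# rejected. Run with: run_pipeline("demo_config.yaml") or the CLI
# `featherkit-cli.R pipeline --config demo_config.yaml`.
seed: 1
out_dir: featherkit-demo
stages: [simulate, morphometry, splice, linkage]
feathers:
  phenotypes: [wildtype, krt75_mt]
  n_per_phenotype: 2
  pixel_scale: 0.15
morphometry:
  length_scale_mm: 3        # backbone smoothing sigma
  fit_window_mm: 3          # tangent line-fit window
  kink_threshold: 5         # deg/mm
cross:
  n_dams: 2
  offspring_per_dam: 6
  n_markers: 40
  n_linked: 5               # first markers fully linked to the trait locus
  call_rate: 0.9937
  disease_allele_freq: 0.001
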