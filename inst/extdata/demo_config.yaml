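# Example pipeline configuration for run_all(). Omitted fields fall back to
# default_run_config(): axis 300-2000 cm-1 step 2, high-resolution scans,
# crop 400-1800, lambda 0.002, 16 elastic / 12 collagen MCR components,
# alpha 0.05.
seed: 1
cohorts:
  murine:
    species: mouse
    region: ascending
    groups:
      - name: WT
        n_maps: 6
      - name: Fbln5KO
        n_maps: 6
      - name: Fbln4SMKO
        n_maps: 6
        disease_components: [ce1_like, cc6_like]
  human:
    species: human
    region: ascending
    warm_start_from: murine
    k_extra: 2
    groups:
      - name: human_control
        n_maps: 3
      - name: aTAA
        n_maps: 3
        disease_components: [ce1_like, cc6_like]
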