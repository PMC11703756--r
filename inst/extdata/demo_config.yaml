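seed: 42
output_dir: leafletdyn_demo
stages:
  membrane:
    enabled: true
    params:
      barrier_height: 4
      n_steps: 50000
      frame_stride: 10
    composition:
      counts: {A: 2}
      thresholds: {A: 0.7}
      interactions:
        - pair: [A, A]
          epsilon: 6
          sigma_r: 0.6
          sigma_z: 0.35
          kappa: 2
  transitions:
    enabled: true
    thresholds: {A: 0.7}
  histogram:
    enabled: true
    mode: intensity_sensitive
  rdf:
    enabled: true
    pair: [A, A]
    mode: full_3d
  clusters:
    enabled: true
    cutoff: 1.0
  fluorescence:
    enabled: true
    n_guvs: 20
    direction: quench
    noise_sd: 2
  areas:
    enabled: true
    n: 10
  fates:
    enabled: true
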