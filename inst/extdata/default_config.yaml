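# Toy end-to-end configuration: small meshes, 3 x 3 grid, fast.
seed: 1
library:
  Nb: 12
  degree: 12
  mesh_level: 2        # 162 vertices per hemisphere
sensors:
  n: 64
grid:
  orders: [6, 9]
  deltas_a: [-2, 0, 2]
  deltas_b: [-2, 0, 2]
simulate:
  n_sources: 2
  correlated: false
  snr_db: 0
  Nt: 210
inversion:
  temporal_modes: 12
output_dir: anatomeg-out
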