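# Default run configuration: published signal constants with the packaged
# calibrated rate set. Keys mirror the model's own symbols.
model_id: model1
provenance: packaged_default
signals:
  E_R: 0.1
  E_Max: 0.9
  Dur_E: 1.0
  G_R: 0.1
  G_Max: 0.9
  Dur_G1: 2.0
  Dur_G2: 7.0
  Width_G: 0.5
  GF: 1.0
  F_T: 5.0
solver:
  rtol: 1.0e-8
  atol: 1.0e-10
  grid: 0.05
analysis:
  intensity: 0.10
  "n": 5000
  seed: 1
  intensities: [0.05, 0.10, 0.15, 0.20, 0.25]
  n_iter: 10000
  t_end: 30
outdir: "."
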