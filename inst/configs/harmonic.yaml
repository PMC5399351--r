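# Harmonic well: detailed-balance case with closed-form stationary
# statistics Var(x) = D*gamma/k / (1 + tau*k/gamma).
seed: 1
out_dir: runs/harmonic
model:
  potential: harmonic
  potential_args:
    k: 1.0
  gamma: 1.0
  D: 1.0
  tau: 0.5
  length_scale: 1.0
sim:
  n_traj: 256
  n_steps: 300000
  dt: 0.0005
  burn_in: 50000
solver:
  nx: 97
  nv: 40
  L: 6.0
analysis:
  nbins: 81
  min_count: 20
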