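# Double-well showcase: gamma = 1, D = 1, tau = 0.7, dt = 1e-3 tau,
# 256 trajectories, 100 tau burn-in (desk-scale version of the reference
# ensemble experiment).
seed: 1
out_dir: runs/double_well
model:
  potential: double_well
  gamma: 1.0
  D: 1.0
  tau: 0.7
  length_scale: 1.0
sim:
  n_traj: 256
  n_steps: 1100000
  dt: 0.0007
  burn_in: 100000
solver:
  nx: 97
  nv: 100
  L: 2.8
analysis:
  nbins: 101
  min_count: 20
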