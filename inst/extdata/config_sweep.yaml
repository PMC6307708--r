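# Rate-fidelity trade-off sweep over activator half-lives.
command: sweep
params:
  tau_x: 1               # overwritten along the sweep grid
  tau_y: 21.64
  tau_z: 21.64
sweep:
  sigma_mode: constrained
  log10_tau_min: -1
  log10_tau_max: 4
  n_points: 25
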