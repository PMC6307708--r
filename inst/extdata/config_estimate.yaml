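# Estimate binned statistics from simulated microcolonies.
# Run: run_pipeline("config_estimate.yaml", out_dir = "...", seed = <int>)
command: estimate
params:
  half_life_x: 30        # minutes; tau_x = half_life / ln 2
  tau_y: 21.64           # stable downstream proteins, dilution-limited
  tau_z: 21.64
  g_y: 1
  g_z: 1
  sigma_mode: constrained
colony:
  division_time: 15      # minutes
  t_end: 60
  n_colonies: 5
estimate:
  statistic: cv
  channel: ch_cfp
  bin_edges: [2, 4, 8, 16, 32]
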