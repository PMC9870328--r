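{
  "comment": "Toy oscillatory two-variable set (same form as the synthetic Class II mode); spikes periodically for constant input above about 0.12.",
  "mode": "toy2var_osc", "variant": "two_var", "dt": 1e-4,
  "phi": 4, "tau": 0.003, "I0": 0, "k": 1,
  "a_fn": 1, "b_fn": -1, "c_fn": -1, "a_fp": -1,
  "a_gn": 0.25, "b_gn": -2.5, "c_gn": -1.5625, "a_gp": 4, "r_g": -0.8
}
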