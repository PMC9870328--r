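{
  "comment": "Synthetic inhibitory regular-spiking mode: as the excitatory set but with a stronger adaptation nullcline, giving more intense spike-frequency adaptation.",
  "mode": "RS_INH", "variant": "three_var", "dt": 1e-4,
  "phi": 4, "tau": 0.003, "I0": 0, "k": 1,
  "a_fn": 1, "b_fn": -1, "c_fn": -1, "a_fp": -1,
  "a_gn": 0.25, "b_gn": -2.5, "c_gn": -1.5625, "a_gp": 4, "r_g": -0.8,
  "eps_q": 0.02, "a_hn": 0.05, "b_hn": -1, "c_hn": 0, "a_hp": 4, "r_h": -0.5
}
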