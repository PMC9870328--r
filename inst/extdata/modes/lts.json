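{
  "comment": "Synthetic low-threshold-spiking mode: extended four-variable set; eta(u) lowers the rebound threshold after sustained hyperpolarization, producing a rebound burst on release; strong spike-frequency adaptation to positive steps.",
  "mode": "LTS", "variant": "four_var_ext", "dt": 1e-4,
  "phi": 4, "tau": 0.003, "I0": 0.03, "k": 1,
  "a_fn": 2, "b_fn": -1, "c_fn": -1, "a_fp": -1,
  "a_gn": 0.25, "b_gn": -2.5, "c_gn": -1.5625, "a_gp": 0.5, "r_g": -0.7,
  "eps_q": 0.003, "a_hn": 0.02, "b_hn": -1, "c_hn": 0, "a_hp": 0.06, "r_h": -0.3,
  "eps_u": 0.003, "v0": 1.3, "alpha_u": 1,
  "eta0": 0.25, "eta1": 1, "r_u": 0.12
}
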