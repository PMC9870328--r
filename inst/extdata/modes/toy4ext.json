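{
  "comment": "Toy extended four-variable set: toy4var with an eta(u) switch on the recovery rate. Not a neuronal fit.",
  "mode": "toy4ext",
  "variant": "four_var_ext",
  "dt": 1e-4,
  "phi": 1, "tau": 1, "I0": 0, "k": 1,
  "a_fn": 1, "b_fn": 0, "c_fn": 0, "a_fp": 1,
  "a_gn": 2, "b_gn": 0, "c_gn": 0, "a_gp": 2, "r_g": 0,
  "eps_q": 0.1, "a_hn": 0.5, "b_hn": 0, "c_hn": 0, "a_hp": 0.5, "r_h": 0,
  "eps_u": 0.01, "v0": 0.2, "alpha_u": 1,
  "eta0": 1, "eta1": 2, "r_u": 0.5
}
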