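{
  "comment": "Documented toy two-variable set used by the test-suite: f(v)=v^2 on both branches, g(v)=2 v^2, unit time scales. Not a neuronal fit.",
  "mode": "toy2var",
  "variant": "two_var",
  "dt": 1e-4,
  "phi": 1, "tau": 1, "I0": 0, "k": 1,
  "a_fn": 1, "b_fn": 0, "c_fn": 0, "a_fp": 1,
  "a_gn": 2, "b_gn": 0, "c_gn": 0, "a_gp": 2, "r_g": 0
}
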