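{
  "comment": "Synthetic parabolic-bursting mode: four-variable set integrated at 1 ms steps; slow q terminates bursts of the bistable fast subsystem while u contributes a slowly varying depolarizing offset. Repetitive bursting without spike-frequency reset; interburst dynamics are of the damped-oscillation type.",
  "mode": "PB", "variant": "four_var", "dt": 1e-3,
  "phi": 4, "tau": 0.03, "I0": 0, "k": 0.04,
  "a_fn": 2, "b_fn": -1, "c_fn": -1, "a_fp": -1,
  "a_gn": 0.25, "b_gn": -2.5, "c_gn": -1.5625, "a_gp": 0.5, "r_g": -0.7,
  "eps_q": 0.01, "a_hn": 0.02, "b_hn": -1, "c_hn": 0, "a_hp": 0.3, "r_h": -0.3,
  "eps_u": 0.02, "v0": 1.3, "alpha_u": 4
}
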