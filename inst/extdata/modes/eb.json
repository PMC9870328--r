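{
  "comment": "Synthetic elliptic-bursting mode: bistable fast subsystem (rest focus + spiking cycle) with slow q terminating and re-igniting bursts; subthreshold oscillations appear between bursts. Stimulus scale k chosen so inputs around 2.75-4.25 drive bursting.",
  "mode": "EB", "variant": "three_var", "dt": 1e-4,
  "phi": 4, "tau": 0.003, "I0": 0, "k": 0.04,
  "a_fn": 2, "b_fn": -1, "c_fn": -1, "a_fp": -1,
  "a_gn": 0.25, "b_gn": -2.5, "c_gn": -1.5625, "a_gp": 0.5, "r_g": -0.7,
  "eps_q": 0.005, "a_hn": 0.02, "b_hn": -1, "c_hn": 0, "a_hp": 0.12, "r_h": -0.3
}
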