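{
  "params": {
    "rho": 1200,
    "Cp": 1500,
    "k_cond": 0.2,
    "eta_pl": 0.9,
    "mu_fric": 0.0200006870843028,
    "K_rad": 0.4,
    "h_wall": 311.858409385182,
    "T_tool": 25,
    "T_crit": 44.898617064298,
    "z_T": 3.000007861956,
    "s_max": 1,
    "RD_0": 0.45,
    "RD_max": 0.95,
    "P_c": 80,
    "E_el": 8000,
    "radius": 0.003,
    "H_final": 0.0034,
    "gap_s": 0.2,
    "speed_min": 1,
    "n_shells": 50,
    "steps_ramp": 200,
    "steps_unload": 40,
    "steps_gap": 100,
    "time_int": false
  },
  "residuals": {
    "min_survival_400MPa": 0.0691571417460448,
    "pre_benefit_250MPa": -0.0806964956421904,
    "log_benefit_374MPa": 0.0875755850477852,
    "gentle_survival_110MPa": 0
  },
  "anchor_values": {
    "min_survival_400MPa": 0.0427662856698418,
    "pre_benefit_250MPa": 0.0275791051307343,
    "log_benefit_374MPa": 0.217515117009557,
    "gentle_survival_110MPa": 1
  },
  "converged": false
}
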