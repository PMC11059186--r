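[
  {
    "name": "Aspisafe NG+",
    "v_res": 8.0, "e_b": 2.1,
    "v_dead": 0.05, "tau": 0.15,
    "v_u0": 0.31, "c_u": 0.04, "k_u": 2.0,
    "v_o0": 1.31, "c_o": 0.03,
    "recommended_min": null, "recommended_max": null,
    "synthetic_parameters": ["v_res", "v_dead", "tau", "v_u0", "c_u", "k_u", "v_o0", "c_o"]
  },
  {
    "name": "Aspisafe NG",
    "v_res": 9.0, "e_b": 1.9,
    "v_dead": 0.10, "tau": 0.20,
    "v_u0": 0.45, "c_u": 0.05, "k_u": 2.0,
    "v_o0": 1.33, "c_o": 0.03,
    "recommended_min": null, "recommended_max": null,
    "synthetic_parameters": ["v_dead", "tau", "v_u0", "c_u", "k_u", "v_o0", "c_o"]
  },
  {
    "name": "SmartCathG",
    "v_res": 1.5, "e_b": 4.0,
    "v_dead": 0.02, "tau": 0.11,
    "v_u0": 0.21, "c_u": 0.06, "k_u": 2.5,
    "v_o0": 2.14, "c_o": 0.04,
    "recommended_min": 0.5, "recommended_max": 2.5,
    "synthetic_parameters": ["v_res", "e_b", "v_dead", "tau", "v_u0", "c_u", "k_u", "v_o0", "c_o"]
  },
  {
    "name": "SmartCath",
    "v_res": 1.0, "e_b": 5.0,
    "v_dead": 0.03, "tau": 0.16,
    "v_u0": 0.30, "c_u": 0.03, "k_u": 2.0,
    "v_o0": 0.90, "c_o": 0.03,
    "recommended_min": 0.5, "recommended_max": 2.5,
    "synthetic_parameters": ["v_res", "e_b", "v_dead", "tau", "v_u0", "c_u", "k_u", "v_o0", "c_o"]
  },
  {
    "name": "Marquat",
    "v_res": 1.5, "e_b": 2.2,
    "v_dead": 0.08, "tau": 0.22,
    "v_u0": 0.46, "c_u": 0.05, "k_u": 1.8,
    "v_o0": 1.82, "c_o": 0.04,
    "recommended_min": 0.5, "recommended_max": 3.0,
    "synthetic_parameters": ["v_res", "v_dead", "tau", "v_u0", "c_u", "k_u", "v_o0", "c_o"]
  },
  {
    "name": "Cooper",
    "v_res": 0.5, "e_b": 15.7,
    "v_dead": 0.10, "tau": 0.20,
    "v_u0": 0.00, "c_u": 0.02, "k_u": 2.5,
    "v_o0": 0.66, "c_o": 0.02,
    "recommended_min": 1.0, "recommended_max": 2.0,
    "synthetic_parameters": ["v_dead", "tau", "c_u", "k_u", "c_o"]
  },
  {
    "name": "Nutrivent",
    "v_res": 3.0, "e_b": 2.9,
    "v_dead": 0.60, "tau": 0.35,
    "v_u0": 0.96, "c_u": 0.05, "k_u": 2.0,
    "v_o0": 2.55, "c_o": 0.05,
    "recommended_min": 4.0, "recommended_max": 4.0,
    "synthetic_parameters": ["v_res", "v_dead", "tau", "v_u0", "c_u", "k_u", "v_o0", "c_o"]
  }
]
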