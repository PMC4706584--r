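{
  "theta": {
    "F": 0.771,
    "Ka": 0.404,
    "CL_lin": 0.111,
    "Vmax": 11.9,
    "Km": 33.9,
    "Vc": 2.91,
    "Q": 0.445,
    "Vp": 3.06
  },
  "covariate_effects": [
    {"parameter": "CL_lin", "covariate": "weight", "kind": "power", "k_cov": 1.04,  "reference": 68},
    {"parameter": "CL_lin", "covariate": "alt",    "kind": "power", "k_cov": 0.144, "reference": 19},
    {"parameter": "Vc",     "covariate": "weight", "kind": "power", "k_cov": 0.443, "reference": 68},
    {"parameter": "Vp",     "covariate": "weight", "kind": "power", "k_cov": 0.500, "reference": 68}
  ],
  "omega": {"F": 0.130, "CL_lin": 0.300, "Vc": 0.191, "Vp": 0.504},
  "sigma_prop": 0.239,
  "sigma_add": 4.48
}
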