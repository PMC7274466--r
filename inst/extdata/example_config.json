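{
  "kinetics": { "lam": 0.7, "rho": 10, "K": 1, "n": 5, "gamma": "mother" },
  "division": { "T_M": 2, "T_D": 3, "pi": 0.6, "eps_S": 0.1, "eps_V": 0 },
  "founder": { "V": 0.07, "S": 0.5 },
  "horizon": 20,
  "thresholds": { "score": 0.5, "prune_floor": 1e-4, "fate_tol": 1e-6, "prion_floor": 1e-6 },
  "conventions": { "founder_cycle": "mother" }
}
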