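{
  "description": "One-time calibration record for the shipped two-level theory defaults: NPT equilibrium densities of the baseline (LL) and target (HL) levels computed with this package's MD engine.",
  "conditions": {
    "n_molecules": 72,
    "temperature_K": 298,
    "pressure_bar": 1,
    "dt_fs": 0.5,
    "tau_T_ps": 0.1,
    "tau_P_ps": 1.0,
    "replicas": 2,
    "run_ps_LL": 35,
    "run_ps_HL": 50,
    "equil_fraction": 0.3,
    "seeds_LL": [611, 612],
    "seeds_HL": [601, 602]
  },
  "rho_LL": 0.9524,
  "rho_LL_replicas": [0.9492, 0.9556],
  "rho_HL": 1.0235,
  "rho_HL_replicas": [1.0293, 1.0177],
  "relative_gap": 0.0747,
  "contract": "0.03 <= |rho_HL - rho_LL| / rho_LL <= 0.10"
}
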