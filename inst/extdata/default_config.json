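{
  "kinetic": {
    "a0": 100,
    "p_prod": 180,
    "c_nat": 0.05,
    "c_it": 0.9,
    "e_dose": 0.6,
    "tau_dose": 1
  },
  "fibrillar": {
    "k_agg": 0.000129091734120271,
    "c_f": 0.00586484562559919,
    "gamma_it": 0.0275531799865653,
    "gamma_iv": 0.00786115270950755,
    "f0": 0
  },
  "washout_it": 0.283333652129111,
  "washout_iv": 0.0584458599467183,
  "t_start": 120,
  "thresholds": {
    "positivity": 35,
    "negativity": 24
  },
  "grid": {
    "t_end": 220,
    "dt": 0.01
  },
  "seed": 1
}
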