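{
  "n_als": 12,
  "n_disease_control": 6,
  "n_mimic": 3,
  "n_non_neurological": 3,
  "strata_weights": [0.275641025641026, 0.391025641025641, 0.333333333333333],
  "d50_medians": [13.62, 28.81, 62.58],
  "d50_sdlog": [0.174, 0.103, 0.238],
  "dx_slope": 0.28,
  "dx_noise_sd": 1.5,
  "age_mean": 63,
  "age_sd": 10,
  "n_visits": 5,
  "visit_spacing_months": 3,
  "rater_sd": 2,
  "nfl_intercept": 4.734,
  "nfl_slope": -0.581,
  "nfl_age_coef": 0.005,
  "nfl_lab_offset": 0.08,
  "nfl_ftd_offset": 0.15,
  "nfl_resid_sd": 0.31,
  "p_lab_b": 0.333333333333333,
  "p_ftd": 0.0384615384615385,
  "p_male": 0.6,
  "phenotype_probs": [0.58974358974359, 0.294871794871795, 0.0769230769230769, 0.0192307692307692, 0.00641025641025641, 0.00641025641025641, 0.00641025641025641],
  "control_log10_mean": [3.18, 3.2, 2.72],
  "control_log10_sd": [0.38, 0.19, 0.27],
  "shift_strength": 1,
  "shift_means": [0.37, 0.25, 0.2],
  "shift_kappa": 12,
  "survival_threshold": 12,
  "frailty_sdlog": 0.25,
  "censor_fraction": 0.378205128205128,
  "seed": 1
}
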