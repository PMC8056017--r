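Synthetic 12-patient toy cohort for smoke tests.

Generated by d50als::build_cohort() with the configuration recorded in
config.json (n_als = 12, n_disease_control = 6, n_mimic = 3,
n_non_neurological = 3, seed = 1). No clinical data; every value is
simulated.
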