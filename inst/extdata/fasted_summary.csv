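# Per-animal fasted energetics summary of the emulated study: mean basal
# metabolic rate (l O2/min) with number of fasted trials, Kleiber ratio,
# mean maximal postprandial rise (l O2/min), SDA scope and postabsorptive
# respiratory exchange ratio. Tt7 is immature, so its fasted measurements
# are resting (RMR), not basal.
animal_id,bmr_l_min,bmr_sd,n_trials,kleiber_ratio,kleiber_sd,max_delta_mr,max_delta_mr_sd,sda_scope,sda_scope_sd,rer,rer_sd
Tt1,0.68,0.04,2,1.45,0.09,0.31,0.26,1.44,0.35,1.00,0.05
Tt2,0.70,0.24,4,1.49,0.50,0.69,0.45,2.24,1.01,0.71,0.04
Tt3,0.95,0.21,8,2.10,0.46,0.40,0.16,1.46,0.24,0.76,0.04
Tt4,0.75,0.18,7,1.69,0.41,0.17,0.14,1.25,0.20,0.86,0.09
Tt5,0.57,0.23,4,1.16,0.47,0.23,0.21,1.50,0.40,0.80,0.10
Tt6,0.73,0.12,9,1.77,0.28,0.03,0.26,1.09,0.35,0.83,0.10
Tt7,0.54,0.12,7,1.37,0.30,0.07,0.09,1.14,0.15,0.75,0.04
Tt8,0.89,0.18,8,1.41,0.26,0.22,0.13,1.28,0.15,0.75,0.04
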