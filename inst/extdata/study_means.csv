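# Study-level printed summary values used as worked-example inputs.
# gamm_auc_133min_l is the model-predicted total O2 volume (l) over the
# 133-min trial window at the marginal covariate profile; its standard
# error is gamm_auc_se_l. bmr values are the study grand means.
quantity,value
mean_intake_kcal,2258
mean_meal_fraction,0.23
mean_mass_kg,183.9
mean_age_yr,24.5
bmr_l_min,0.73
bmr_sd_l_min,0.14
gamm_auc_133min_l,116.7
gamm_auc_se_l,7.1
trial_window_min,133
tail_rmr_l_min,0.8
tail_end_min,170
marginal_profile_mass_kg,179.4
marginal_profile_age_yr,21.4
marginal_profile_pool_temp_c,22.8
marginal_profile_male_fraction,0.76
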