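quantity,value
n_included,2297
age_baseline_mean,74.5
age_baseline_sd,4.7
n_female,1399
followup_years_mean,5.2
followup_years_sd,0.2
solidity_mean,0.19
solidity_sd,0.12
convexity_mean,1.03
convexity_sd,0.18
concavity_index_mean,1.27
concavity_index_sd,0.15
fd_pvc_mean,1.71
fd_pvc_sd,0.15
eccentricity_mean,0.61
eccentricity_sd,0.07
fd_deep_mean,1.70
fd_deep_sd,0.14
wmh_volume_ml_baseline_mean,16.56
wmh_volume_ml_baseline_sd,17.21
wmh_volume_ml_followup_mean,22.32
wmh_volume_ml_followup_sd,22.18
wmh_volume_ml_change_sd,7.74
n_deep_analysed,2293
subcortical_infarct_baseline_n,153
subcortical_infarct_followup_n,221
subcortical_infarct_new_n,68
microbleed_baseline_n,381
microbleed_followup_n,680
microbleed_new_n,299
epvs_baseline_n,358
epvs_followup_n,397
epvs_new_n,39
cerebellar_infarct_baseline_n,434
cerebellar_infarct_followup_n,596
cerebellar_infarct_new_n,162
cortical_infarct_baseline_n,176
cortical_infarct_followup_n,299
cortical_infarct_new_n,123
excluded_death_n,505
excluded_disability_or_refused_n,859
excluded_lost_to_followup_n,104
excluded_claustrophobia_n,86
excluded_mri_contraindication_n,116
excluded_technical_n,2
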