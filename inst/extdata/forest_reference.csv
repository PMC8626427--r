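quantity,value,units
prescribed_burn_mean_annual_area,3071,km2
prescribed_burn_sd_annual_area,732,km2
forest_study_area,324873,km2
yslf_eligible_area,155384,km2
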