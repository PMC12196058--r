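name,value
nir_coef_mean,1.86
nir_coef_sd,1.51
nir_coef_margin,4.88
ma2a_merged_rmsep_avg,67.21
uve_ma2a_rmsep_avg,65.92
uve_selected_fraction_pct,41
uve_selected_params_pct,79
n_predictors_merged,273
ma1_internal_rmsecv_dv50,19.7
ma1_internal_rmsep_dv50,19.3
block_cv_rmsecv_dv50,34.7
seq_cv_external_rmsep_dv50,38.8
block_cv_external_rmsep_dv50,44.1
lod_rmsep_pct,1.078
lod_rmsec_pct,1.064
lod_rmsecv_pct,1.347
lod_r2_cal,0.936
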