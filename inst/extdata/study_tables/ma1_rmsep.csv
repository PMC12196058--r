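target,nir_all,merged_all,nir_nonoutlier,merged_nonoutlier,p_one_tailed
dv10,60.4,39.4,53.7,30.4,0.0118
dv50,90.6,57.9,68.3,38.8,0.0171
dv90,151.6,136.7,111.1,91.1,0.326
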