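test_batches,nir_rmsecv,nir_r2_cv,nir_rmsep,nir_r2_test,merged_rmsecv,merged_r2_cv,merged_rmsep,merged_r2_test
"0930, 1129, 1229",69.90,0.732,91.45,0.649,34.87,0.933,62.63,0.858
"0920, 1011, 1213",72.17,0.759,96.35,0.618,44.20,0.910,77.00,0.621
"0802, 1128, 1212",68.06,0.779,77.87,0.581,40.99,0.920,56.83,0.827
"1005, 1203, 1230",60.67,0.762,113.54,0.576,39.59,0.899,71.39,0.823
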