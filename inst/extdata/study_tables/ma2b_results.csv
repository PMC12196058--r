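batch,nir_rmsep,nir_r2_test,merged_rmsep,merged_r2_test
0802,57.53,0.811,64.19,0.861
0920,101.0,0.281,86.99,0.446
0930,117.2,0.722,76.50,0.876
1005,135.5,0.471,67.64,0.934
1011,70.81,0.840,33.88,0.947
1128,98.48,0.578,41.31,0.884
1129,49.97,0.824,40.82,0.906
1203,102.3,0.761,49.97,0.961
1212,59.42,0.797,54.10,0.847
1213,81.70,0.680,87.88,0.457
1229,40.45,0.897,62.94,0.921
1230,46.78,0.865,43.95,0.947
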