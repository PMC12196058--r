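experiment,rmsep,n_selected,n_params_selected
1,64.03,68,14
2,81.05,123,12
3,53.95,102,13
4,64.64,159,15
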