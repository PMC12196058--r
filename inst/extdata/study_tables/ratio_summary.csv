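approach,model,rpd,rer,prl,rpiq
ma1,nir,2.03,11.3,0.97,2.81
ma1,merged,3.57,19.9,0.54,5.02
ma2a,nir,1.46,8.15,1.35,2.03
ma2a,merged,2.06,11.5,0.96,2.86
ma2b,nir,1.73,9.64,1.14,2.40
ma2b,merged,2.34,13.1,0.84,3.25
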