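parameter,abs_coef
airflow_rate,68.63
runtime,20.19
atomizing_pressure,19.77
pht_out_temp,13.83
inlet_air_temp,12.66
plenum_pressure,12.49
exhaust_pressure,11.70
pht_in_abs_hum,8.66
pht_in_rel_hum,7.96
pht_out_rel_hum,7.73
pht_out_abs_hum,5.92
exhaust_temp,5.08
pht_out_pressure,5.04
product_temp,3.99
pht_in_pressure,3.80
prod_filt_diff_pressure,3.25
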