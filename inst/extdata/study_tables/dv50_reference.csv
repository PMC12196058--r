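group,start_point,endpoint,mean,st_dev,min,max,range,q3_q1,lab_error
1020,202.1,75.0,379.6,180.0,64.3,661.0,596.7,309.4,NA
1214,149.7,511.7,416.0,192.7,99.4,765.6,666.2,315.1,NA
non_outliers,144.5,300.9,314.0,138.6,52.4,824.7,772.3,192.2,70.3
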