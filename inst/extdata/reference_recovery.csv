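compartment,organ,mean_rr,sd_rr
liver_1,liver,86.4,10.6
liver_2,liver,89.6,4.0
rectum_superficial,rectum,85.4,22.2
rectum_profound,rectum,70.3,8.8
stomach_superficial,stomach,87.0,11.4
stomach_profound,stomach,91.0,4.9
peritoneum_1,peritoneum,73.0,9.2
peritoneum_2,peritoneum,75.5,10.9
peritoneum_3,peritoneum,73.9,18.0
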