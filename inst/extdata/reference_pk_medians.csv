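compartment,organ,n,auc_0_last,t_half,c_max,t_max
liver_1,liver,7,115.0,33.7,1.0,103.5
liver_2,liver,5,125.0,32.6,1.1,100.6
rectum_superficial,rectum,4,104.27,36.9,0.75,124.4
rectum_profound,rectum,4,58.00,35.5,0.45,115.5
stomach_superficial,stomach,7,118.34,34.5,1.00,102.9
stomach_profound,stomach,6,80.64,41.0,0.63,108.0
peritoneum_1,peritoneum,8,284.1,21.3,2.6,104.8
peritoneum_2,peritoneum,6,306.4,15.9,2.7,114.6
peritoneum_3,peritoneum,6,357.1,21.6,3.11,110.6
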