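sample,predicted_oct_min,applied_ct_min,apf_weighted_N,apf_sd,tactile,tactile_sd,chewiness,chewiness_sd,pct_cooked
SCT,66.1,66.1,0.64,0.13,6.8,0.94,7.1,2.1,97.6
LCT,75.3,75.3,0.63,0.11,7.0,0.60,7.3,6.0,98.9
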