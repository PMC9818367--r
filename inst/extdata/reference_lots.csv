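lot_id,origin_class,tsm_whole_g,tsm_mb_g,tsm_img_g,pct_mb,pct_img,L,a,b,moisture_pct
SCT,SCT,24.4,33.35,16.65,47.6,52.4,56.0,3.2,25.2,13
LCT,LCT,34.1,33.64,35.49,75.0,25.0,61.6,5.1,25.9,13
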