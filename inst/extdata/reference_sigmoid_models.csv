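sample,maturity,parameter,a,x0,b,printed_sign,r2,signif,oct_pred,pct_cooked
SCT,MB,APF,100.1,13.88,5.6,minus,0.9964,***,42,97
SCT,IMG,APF,101.79,29.28,8.6,minus,0.9960,***,67.7,99
SCT,TOTAL,APF,103.5,21.9,9.4,minus,0.9964,***,66.1,99
LCT,MB,APF,101.16,31.1,8.4,minus,0.9948,***,74.29,99
LCT,IMG,APF,99.62,44.83,6.5,minus,0.9968,***,79.21,99
LCT,TOTAL,APF,100.27,44.5,7.5,minus,0.9964,***,75.3,99
SCT,MB,AAPF,106.09,18.88,13.22,minus,0.9702,***,86.32,99
SCT,IMG,AAPF,88.03,12.99,4.75,minus,0.9951,***,81.95,99
SCT,TOTAL,AAPF,127.83,40.19,23.9,minus,0.9767,***,85.78,99
LCT,MB,AAPF,101.16,31.1,8.4,minus,0.9948,***,81.40,99
LCT,IMG,AAPF,99.62,44.83,6.5,minus,0.9968,***,75.93,99
LCT,TOTAL,AAPF,100.27,44.57,7.5,minus,0.9964,***,80.31,99
SCT,MB,GAPF,96.87,17.59,6.6,minus,0.99,***,>100,97
SCT,IMG,GAPF,97.05,36.76,4.8,minus,0.9960,***,>100,97
SCT,TOTAL,GAPF,100.6,21.0,6.7,minus,0.9975,***,61,99
LCT,MB,GAPF,101.16,31.1,8.4,minus,0.9948,***,65.00,99
LCT,IMG,GAPF,99.62,44.83,6.5,minus,0.9968,***,>100,97
LCT,TOTAL,GAPF,101.37,33.1,8.2,minus,0.9976,***,65.54,99
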