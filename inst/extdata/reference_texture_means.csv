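sample,maturity,cooking_time_min,parameter,average,average_sd,weighted,weighted_sd
SCT,MB,20,APF,0.76,0.35,0.37,0.17
SCT,MB,30,APF,0.73,0.32,0.34,0.15
SCT,MB,40,APF,0.46,0.30,0.23,0.15
SCT,MB,50,APF,0.45,0.18,0.22,0.09
SCT,MB,60,APF,0.38,0.14,0.14,0.05
LCT,MB,20,APF,1.34,0.53,1.23,0.48
LCT,MB,30,APF,1.18,0.48,0.99,0.40
LCT,MB,40,APF,0.87,0.37,0.67,0.29
LCT,MB,50,APF,0.73,0.33,0.55,0.29
LCT,MB,60,APF,0.57,0.21,0.42,0.16
SCT,IMG,20,APF,1.06,0.46,0.97,0.42
SCT,IMG,30,APF,0.83,0.43,0.75,0.39
SCT,IMG,40,APF,0.67,0.25,0.53,0.20
SCT,IMG,50,APF,0.54,0.24,0.41,0.18
SCT,IMG,60,APF,0.51,0.12,0.38,0.12
LCT,IMG,20,APF,1.63,0.53,1.50,0.75
LCT,IMG,30,APF,1.18,0.48,1.00,0.38
LCT,IMG,40,APF,0.87,0.37,0.71,0.25
LCT,IMG,50,APF,0.73,0.26,0.52,0.18
LCT,IMG,60,APF,0.65,0.19,0.40,0.12
SCT,TOTAL,20,APF,0.91,0.43,0.73,0.31
SCT,TOTAL,30,APF,0.78,0.38,0.60,0.29
SCT,TOTAL,40,APF,0.56,0.29,0.41,0.18
SCT,TOTAL,50,APF,0.41,0.17,0.49,0.21
SCT,TOTAL,60,APF,0.37,0.10,0.45,0.14
LCT,TOTAL,20,APF,1.49,0.69,1.32,0.57
LCT,TOTAL,30,APF,1.19,0.46,1.01,0.40
LCT,TOTAL,40,APF,0.88,0.34,0.70,0.28
LCT,TOTAL,50,APF,0.73,0.29,0.57,0.23
LCT,TOTAL,60,APF,0.61,0.20,0.45,0.15
SCT,MB,20,AAPF,4.94,3.06,2.40,1.48
SCT,MB,30,AAPF,4.55,2.14,2.11,0.99
SCT,MB,40,AAPF,4.47,3.25,2.29,1.66
SCT,MB,50,AAPF,4.00,2.34,2.00,1.17
SCT,MB,60,AAPF,3.51,2.18,1.30,0.81
LCT,MB,20,AAPF,6.71,3.56,6.13,3.25
LCT,MB,30,AAPF,6.45,3.93,5.45,3.32
LCT,MB,40,AAPF,4.50,2.30,3.46,1.77
LCT,MB,50,AAPF,3.56,2.06,2.69,1.56
LCT,MB,60,AAPF,2.86,1.61,2.12,1.20
SCT,IMG,20,AAPF,10.78,3.06,9.87,4.34
SCT,IMG,30,AAPF,4.55,2.14,6.58,2.37
SCT,IMG,40,AAPF,4.47,3.25,4.62,1.71
SCT,IMG,50,AAPF,4.49,1.77,3.42,1.35
SCT,IMG,60,AAPF,4.24,1.86,3.17,1.39
LCT,IMG,20,AAPF,8.94,3.56,8.22,4.28
LCT,IMG,30,AAPF,6.45,3.93,5.76,2.89
LCT,IMG,40,AAPF,4.50,2.30,4.23,1.71
LCT,IMG,50,AAPF,3.83,1.69,2.71,1.19
LCT,IMG,60,AAPF,3.58,1.37,2.21,0.84
SCT,TOTAL,20,AAPF,7.86,4.92,8.69,3.06
SCT,TOTAL,30,AAPF,5.88,2.74,6.35,1.78
SCT,TOTAL,40,AAPF,5.09,2.82,5.21,1.69
SCT,TOTAL,50,AAPF,4.24,2.07,4.28,1.26
SCT,TOTAL,60,AAPF,3.86,2.04,3.96,1.13
LCT,TOTAL,20,AAPF,7.83,4.23,7.47,3.58
LCT,TOTAL,30,AAPF,6.67,3.66,6.58,3.22
LCT,TOTAL,40,AAPF,4.90,2.23,4.77,1.75
LCT,TOTAL,50,AAPF,3.69,1.87,3.64,1.48
LCT,TOTAL,60,AAPF,3.20,1.52,3.07,1.13
SCT,MB,20,GAPF,0.25,0.22,0.09,0.08
SCT,MB,30,GAPF,0.09,0.03,0.05,0.02
SCT,MB,40,GAPF,0.09,0.03,0.03,0.01
SCT,MB,50,GAPF,0.08,0.04,0.04,0.02
SCT,MB,60,GAPF,0.06,0.03,0.02,0.01
LCT,MB,20,GAPF,0.19,0.11,0.17,0.10
LCT,MB,30,GAPF,0.13,0.05,0.11,0.05
LCT,MB,40,GAPF,0.11,0.09,0.09,0.07
LCT,MB,50,GAPF,0.08,0.08,0.06,0.06
LCT,MB,60,GAPF,0.05,0.02,0.04,0.02
SCT,IMG,20,GAPF,0.29,0.22,0.27,0.27
SCT,IMG,30,GAPF,0.09,0.03,0.12,0.05
SCT,IMG,40,GAPF,0.09,0.03,0.07,0.02
SCT,IMG,50,GAPF,0.08,0.03,0.06,0.02
SCT,IMG,60,GAPF,0.07,0.03,0.05,0.02
LCT,IMG,20,GAPF,0.21,0.11,0.19,0.15
LCT,IMG,30,GAPF,0.13,0.05,0.12,0.05
LCT,IMG,40,GAPF,0.11,0.09,0.07,0.02
LCT,IMG,50,GAPF,0.08,0.04,0.05,0.03
LCT,IMG,60,GAPF,0.06,0.03,0.04,0.02
SCT,TOTAL,20,GAPF,0.27,0.26,0.28,0.18
SCT,TOTAL,30,GAPF,0.11,0.05,0.12,0.04
SCT,TOTAL,40,GAPF,0.09,0.03,0.09,0.02
SCT,TOTAL,50,GAPF,0.08,0.03,0.08,0.02
SCT,TOTAL,60,GAPF,0.07,0.03,0.07,0.02
LCT,TOTAL,20,GAPF,0.20,0.14,0.19,0.12
LCT,TOTAL,30,GAPF,0.13,0.06,0.13,0.05
LCT,TOTAL,40,GAPF,0.10,0.07,0.12,0.06
LCT,TOTAL,50,GAPF,0.08,0.06,0.11,0.05
LCT,TOTAL,60,GAPF,0.06,0.00,0.10,0.02
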