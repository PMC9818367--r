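sample,maturity,parameter,input_kind,y0,a,k,r2,signif,oct_range,oct_pred
SCT,MB,APF,average,9.86,112.2,0.023,0.8942,ns,<20,<10
SCT,MB,APF,weighted,2.51,60.23,0.021,0.9401,**,<20,<10
SCT,IMG,APF,average,39.24,170.1,0.044,0.9960,**,30-40,31.5
SCT,IMG,APF,weighted,23.34,182.14,0.043,0.992,**,20-30,26.8
SCT,TOTAL,APF,average,27.21,133.8,0.034,0.9782,*,20-30,26.8
SCT,TOTAL,APF,weighted,14.79,102.9,0.031,0.934,ns,<20,14.2
LCT,MB,APF,average,-71.02,268.1,0.012,0.9868,*,40-50,46.3
LCT,MB,APF,weighted,1.14,218.5,0.027,0.9870,*,30-40,36.4
LCT,IMG,APF,average,48.71,319.4,0.049,0.9988,**,40-50,46.3
LCT,IMG,APF,weighted,21.88,343.9,0.048,1,***,40-50,36.2
LCT,TOTAL,APF,average,26.41,240.18,0.032,0.9959,**,40-50,46.3
LCT,TOTAL,APF,weighted,16.73,243.9,0.035,0.995,**,30-40,37.4
SCT,MB,AAPF,average,0,600.3,0.0048,0.7533,ns,40-50,59.45
SCT,MB,AAPF,weighted,0,312.7,0.0107,0.671,ns,<20,<10
SCT,IMG,AAPF,average,430.9,3020.4,0.0704,0.9991,***,40-60,>70
SCT,IMG,AAPF,weighted,240.7,2557.7,0.0601,0.938,**,40-50,41.6
SCT,TOTAL,AAPF,average,331.1,1245.5,0.0490,0.9952,**,40-50,47.7
SCT,TOTAL,AAPF,weighted,343.4,1656.5,0.0559,0.999,**,30-40,48.9
LCT,MB,AAPF,average,8.01,4169.6,0.2730,0.9856,*,20-30,28.0
LCT,MB,AAPF,weighted,2.77,76.55,0.1253,0.961,*,<20,18.9
LCT,IMG,AAPF,average,7.12,283.2,0.1258,0.9995,***,20-30,36.7
LCT,IMG,AAPF,weighted,5.11,283.1,0.1150,1,***,30-40,33.4
LCT,TOTAL,AAPF,average,7.61,517.2,0.1620,0.9966,**,30-40,33.2
LCT,TOTAL,AAPF,weighted,7.51,441.5,0.1523,0.998,**,30-40,34.1
SCT,MB,GAPF,average,0,1100.4,0.0211,0.9369,**,40-50,42.3
SCT,MB,GAPF,weighted,0,1162.1,0.0268,0.9640,**,30-40,35.5
SCT,IMG,GAPF,average,164.9,1528.5,0.0353,0.9916,**,40-50,47.3
SCT,IMG,GAPF,weighted,150.7,1695.1,0.0421,0.992,**,40-50,41.1
SCT,TOTAL,GAPF,average,-59.7,1325.1,0.0210,0.9831,*,40-50,45.6
SCT,TOTAL,GAPF,weighted,-2.91,1262.7,0.0257,0.986,*,40-50,39.8
LCT,MB,GAPF,average,-4.44,34.8,0.0208,0.9700,*,40-50,42.5
LCT,MB,GAPF,weighted,-0.64,35.1,0.0329,0.9752,*,30-40,36.7
LCT,IMG,GAPF,average,5.01,60.0,0.0646,0.9919,**,40-50,38.50
LCT,IMG,GAPF,weighted,4.07,64.7,0.0681,0.992,**,30-40,35.31
LCT,TOTAL,GAPF,average,3.08,45.1,0.052,0.9948,**,40-50,36
LCT,TOTAL,GAPF,weighted,3.46,42.1,0.0465,0.996,**,20-30,40.2
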