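parameter,threshold,unit,doneness_score
APF,0.80,N,6.5
AAPF,4.45,N.s,6.5
GAPF,0.10,N/s,6.5
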