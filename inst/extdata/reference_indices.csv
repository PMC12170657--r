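mode,drug,W,WW,H,D,DH,suspect
heavy,ALP,926,2770,81.4698,2845,24.1903,FALSE
heavy,AMT,882,2780,70.7087,2581,26.2091,TRUE
heavy,AMX,1075,3398,85.8329,3291,25.4936,TRUE
heavy,BSP,2514,13028,102.7360,3764,57.3198,FALSE
heavy,CLM,995,3194,78.0429,2861,28.6732,FALSE
heavy,DSP,882,2780,70.7087,2581,26.2091,TRUE
heavy,DVF,897,2846,71.6540,1329,46.9409,TRUE
heavy,DZM,726,2077,69.4905,1901,24.9069,FALSE
heavy,FLX,1292,4946,77.8563,1772,54.1895,TRUE
heavy,IMP,882,2780,70.7087,2581,26.2091,TRUE
heavy,LRZ,1034,3076,86.5452,2601,33.9740,TRUE
heavy,NTP,882,2780,70.7087,2581,26.2091,TRUE
heavy,OZP,928,2731,80.6476,2362,30.8960,TRUE
heavy,PTP,882,2780,70.7087,2581,26.2091,TRUE
heavy,TMP,979,3081,78.4611,2808,30.3429,FALSE
all-h,ALP,2936,10289,168.8604,7858,68.2119,FALSE
all-h,AMT,5252,20371,239.9619,12117,126.6943,FALSE
all-h,AMX,3564,12697,193.5572,9689,78.4991,FALSE
all-h,BSP,12709,69193,366.6186,18125,244.3614,FALSE
all-h,CLM,5462,21023,250.8310,12557,134.2503,FALSE
all-h,DSP,4538,16736,226.4617,10943,114.0553,FALSE
all-h,DVF,4836,17076,248.9564,7008,179.4176,FALSE
all-h,DZM,2497,8380,154.1603,5741,71.3523,FALSE
all-h,FLX,4433,17760,198.7027,6065,148.3364,FALSE
all-h,IMP,5462,21023,250.8310,12557,134.2503,FALSE
all-h,LRZ,2142,7027,139.4702,5038,62.4229,FALSE
all-h,NTP,4346,16147,216.0927,10521,106.9993,FALSE
all-h,OZP,2142,7027,139.4702,5038,62.4229,FALSE
all-h,PTP,4267,15583,218.2697,10307,111.5984,FALSE
all-h,TMP,6278,24110,279.5762,14063,156.9178,FALSE
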