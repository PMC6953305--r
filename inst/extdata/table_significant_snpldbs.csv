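trait,snpldb,chromosome,p_value,r2_pct
BRR,4_BLOCK_17882078_17907416,4,0.00004,54.9
BRR,S5_12092551,5,0.00083,49.1
MRR,4_BLOCK_17882078_17907416,4,0.00007,53.6
MRR,S5_12092551,5,0.00078,49.4
HRR,4_BLOCK_17882078_17907416,4,0.00051,52.0
HRR,S5_12092551,5,0.00073,49.9
HRR,8_BLOCK_26862470_27057202,8,0.00080,35.5
PCG,4_BLOCK_17882078_17907416,4,0.00093,51.1
CAS,1_BLOCK_937039_1124378,1,0.00352,34.3
CAS,S2_22375014,2,0.00277,29.4
CAS,2_BLOCK_23246549_23402926,2,0.00978,19.6
CAS,3_BLOCK_2736967_2935082,3,0.00679,33.6
CAS,4_BLOCK_17882078_17907416,4,0.00135,59.0
CAS,S5_12092551,5,0.00226,43.1
CAS,S8_15013758,8,0.00232,45.6
CAS,8_BLOCK_26862470_27057202,8,0.00483,42.9
CAS,S9_10804219,9,0.00431,47.8
CAS,S9_21092077,9,0.00520,26.4
CAS,11_BLOCK_16710912_16770852,11,0.00319,60.9
CAS,12_BLOCK_3214955_3413848,12,0.00702,23.2
CD,4_BLOCK_17882078_17907416,4,0.00075,52.2
GT,4_BLOCK_17882078_17907416,4,0.00009,50.3
GC,4_BLOCK_17882078_17907416,4,0.00009,50.3
GC,S5_12092551,5,0.00057,41.3
AC,S2_22375014,2,0.00343,47.8
AC,2_BLOCK_23246549_23402926,2,0.00902,20.0
AC,3_BLOCK_2736967_2935082,3,0.00909,51.0
AC,3_BLOCK_26597888_26785589,3,0.00879,23.6
AC,4_BLOCK_17882078_17907416,4,0.00281,54.3
AC,S5_12092551,5,0.00235,42.9
AC,S8_15013758,8,0.00124,49.5
AC,8_BLOCK_26862470_27057202,8,0.00707,49.8
AC,S9_10804219,9,0.00731,43.7
AC,9_BLOCK_20278565_20464993,9,0.00954,19.8
AC,S9_21092077,9,0.00533,26.2
AC,11_BLOCK_16710912_16770852,11,0.00164,63.5
AC,11_BLOCK_23565814_23565855,11,0.00973,20.9
AC,11_BLOCK_24442254_24636131,11,0.00759,31.9
AC,12_BLOCK_3214955_3413848,12,0.00791,22.6
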