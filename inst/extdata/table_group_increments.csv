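trait,snpldb,elite_genotype,chromosome,position_bp,gene,mean_homozygous,mean_heterozygous,increment_pct
BRR,4_BLOCK_17882078_17907416,A/C,4,17907065,Os04g0368800,68.59,75.64,10.28
BRR,S5_12092551,A/T,5,12092551,,,,
MRR,4_BLOCK_17882078_17907416,A/C,4,17907065,Os04g0368800,59.90,66.26,10.62
MRR,S5_12092551,A/T,5,12092551,,,,
HRR,4_BLOCK_17882078_17907416,A/C,4,17907065,Os04g0368800,53.40,60.26,12.85
HRR,S5_12092551,A/T,5,12092551,,,,
HRR,8_BLOCK_26862470_27057202,C/T,8,26969210,Os08g0539400,51.56,60.50,17.35
PCG,4_BLOCK_17882078_17907416,A/C,4,17907065,Os04g0368800,48.63,43.46,-10.63
CAS,1_BLOCK_937039_1124378,A/G,1,973135,Os01g0117200,29.00,27.58,-4.89
CAS,S2_22375014,C/T,2,22375014,,,,
CAS,2_BLOCK_23246549_23402926,A/C,2,23391787,Os02g0599200,27.75,25.65,-7.55
CAS,3_BLOCK_2736967_2935082,C/T,3,2924237,Os03g0153000,28.80,27.58,-2.81
CAS,3_BLOCK_2736967_2935082,A/G,3,2924244,Os03g0153000,28.80,27.58,-2.81
CAS,4_BLOCK_17882078_17907416,A/C,4,17907065,Os04g0368800,27.85,22.95,-17.58
CAS,S5_12092551,A/T,5,12092551,,,,
CAS,S8_15013758,G/T,8,15013758,,,,
CAS,8_BLOCK_26862470_27057202,C/T,8,26969210,Os08g0539400,27.28,21.09,-22.68
CAS,S9_10804219,A/C,9,10804219,Os09g0345600,28.13,27.03,-3.90
CAS,S9_21092077,A/C,9,21092077,,,,
CAS,11_BLOCK_16710912_16770852,A/C,11,16750908,Os11g0479100,28.94,27.67,-4.37
CAS,11_BLOCK_16710912_16770852,A/T,11,16750919,Os11g0479100,28.94,27.67,-4.37
CAS,12_BLOCK_3214955_3413848,A/C,12,3315860,Os12g0165000,27.37,23.71,-13.38
CAS,12_BLOCK_3214955_3413848,G/T,12,3315865,Os12g0165000,27.37,23.71,-13.38
CD,4_BLOCK_17882078_17907416,A/C,4,17907065,Os04g0368800,1.96,1.76,-10.47
GT,4_BLOCK_17882078_17907416,A/C,4,17907065,Os04g0368800,2.83,4.06,43.57
GC,4_BLOCK_17882078_17907416,A/C,4,17907065,Os04g0368800,47.91,52.17,8.90
GC,S5_12092551,A/T,5,12092551,,,,
AC,S2_22375014,C/T,2,22375014,,,,
AC,2_BLOCK_23246549_23402926,A/C,2,23391787,Os02g0599200,20.49,18.60,-9.25
AC,3_BLOCK_2736967_2935082,C/T,3,2924237,Os03g0153000,21.15,20.30,-3.99
AC,3_BLOCK_2736967_2935082,A/G,3,2924244,Os03g0153000,21.15,20.30,-3.99
AC,3_BLOCK_26597888_26785589,A/G,3,26685420,,,,
AC,3_BLOCK_26597888_26785589,A/G,3,26685423,,,,
AC,4_BLOCK_17882078_17907416,A/C,4,17907065,Os04g0368800,20.62,16.38,-20.57
AC,S5_12092551,A/T,5,12092551,,,,
AC,S8_15013758,G/T,8,15013758,,,,
AC,8_BLOCK_26862470_27057202,C/T,8,26969210,Os08g0539400,20.09,14.73,-26.65
AC,S9_10804219,A/C,9,10804219,Os09g0345600,20.86,19.89,-4.67
AC,9_BLOCK_20278565_20464993,C/G,9,20406303,,,,
AC,S9_21092077,A/C,9,21092077,,,,
AC,11_BLOCK_16710912_16770852,A/C,11,16750908,Os11g0479100,21.89,20.58,-5.97
AC,11_BLOCK_16710912_16770852,A/T,11,16750919,Os11g0479100,21.89,20.58,-5.97
AC,11_BLOCK_23565814_23565855,A/T,11,23565848,Os11g0609700,20.16,17.69,-12.23
AC,11_BLOCK_24442254_24636131,A/C,11,24442308,,,,
AC,12_BLOCK_3214955_3413848,A/C,12,3315860,Os12g0165000,20.14,16.91,-16.04
AC,12_BLOCK_3214955_3413848,G/T,12,3315865,Os12g0165000,20.14,16.91,-16.04
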