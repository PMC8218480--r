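table,subset,group,year,millions
1,all,total,2015,159.07
1,all,total,2060,439.34
1,all,without_impairment,2015,141.15
1,all,without_impairment,2060,343.16
1,all,impaired,2015,17.920
1,all,impaired,2060,96.184
1,female,total,2015,81.175
1,female,total,2060,221.45
1,female,without_impairment,2015,69.782
1,female,without_impairment,2060,164.51
1,female,impaired,2015,11.393
1,female,impaired,2060,56.943
1,male,total,2015,77.90
1,male,total,2060,217.88
1,male,without_impairment,2015,71.376
1,male,without_impairment,2060,178.64
1,male,impaired,2015,6.527
1,male,impaired,2060,39.241
2,all,impaired_65-74,2015,3.180
2,all,impaired_65-74,2060,4.009
2,all,impaired_75-84,2015,8.650
2,all,impaired_75-84,2060,22.329
2,all,impaired_85+,2015,6.090
2,all,impaired_85+,2060,69.846
2,female,impaired_65-74,2015,1.863
2,female,impaired_65-74,2060,2.346
2,female,impaired_75-84,2015,5.404
2,female,impaired_75-84,2060,13.425
2,female,impaired_85+,2015,4.126
2,female,impaired_85+,2060,41.172
2,male,impaired_65-74,2015,1.317
2,male,impaired_65-74,2060,1.663
2,male,impaired_75-84,2015,3.245
2,male,impaired_75-84,2060,8.904
2,male,impaired_85+,2015,1.964
2,male,impaired_85+,2060,28.674
3,all,ADL_ONLY,2015,3.679
3,all,ADL_ONLY,2060,23.984
3,all,CI_ONLY,2015,11.443
3,all,CI_ONLY,2060,47.848
3,all,CI_AND_ADL,2015,2.798
3,all,CI_AND_ADL,2060,24.352
3,female,ADL_ONLY,2015,1.650
3,female,ADL_ONLY,2060,10.691
3,female,CI_ONLY,2015,7.728
3,female,CI_ONLY,2060,30.141
3,female,CI_AND_ADL,2015,2.016
3,female,CI_AND_ADL,2060,16.110
3,male,ADL_ONLY,2015,2.029
3,male,ADL_ONLY,2060,13.293
3,male,CI_ONLY,2015,3.716
3,male,CI_ONLY,2060,17.706
3,male,CI_AND_ADL,2015,0.782
3,male,CI_AND_ADL,2060,8.242
4,65-74,ADL_ONLY,2015,0.934
4,65-74,ADL_ONLY,2060,1.129
4,65-74,CI_ONLY,2015,2.076
4,65-74,CI_ONLY,2060,2.717
4,65-74,CI_AND_ADL,2015,0.170
4,65-74,CI_AND_ADL,2060,0.163
4,75-84,ADL_ONLY,2015,1.598
4,75-84,ADL_ONLY,2060,4.163
4,75-84,CI_ONLY,2015,6.003
4,75-84,CI_ONLY,2060,15.723
4,75-84,CI_AND_ADL,2015,1.049
4,75-84,CI_AND_ADL,2060,2.443
4,85+,ADL_ONLY,2015,1.147
4,85+,ADL_ONLY,2060,18.692
4,85+,CI_ONLY,2015,3.365
4,85+,CI_ONLY,2060,29.408
4,85+,CI_AND_ADL,2015,1.578
4,85+,CI_AND_ADL,2060,21.764
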