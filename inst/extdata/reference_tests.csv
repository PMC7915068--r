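table,measure,test,outliers_removed,subject,stride_type,statistic,df,p
gap_kw,leg_gap,kruskal_wallis,no,S1,Fast,27.53,1,0.000
gap_kw,leg_gap,kruskal_wallis,no,S1,Slow,1.93,1,0.165
gap_kw,leg_gap,kruskal_wallis,no,S1,RightAntalgic,40.08,1,0.000
gap_kw,leg_gap,kruskal_wallis,no,S1,LeftAntalgic,0.34,1,0.557
gap_kw,leg_gap,kruskal_wallis,no,S1,All,71.46,4,0.000
gap_kw,leg_gap,kruskal_wallis,no,S2,Fast,1.71,1,0.190
gap_kw,leg_gap,kruskal_wallis,no,S2,Slow,1.42,1,0.233
gap_kw,leg_gap,kruskal_wallis,no,S2,RightAntalgic,51.48,1,0.000
gap_kw,leg_gap,kruskal_wallis,no,S2,LeftAntalgic,26.49,1,0.000
gap_kw,leg_gap,kruskal_wallis,no,S2,All,100.52,4,0.000
gap_kw,leg_gap,kruskal_wallis,no,S3,Fast,4.19,1,0.041
gap_kw,leg_gap,kruskal_wallis,no,S3,Slow,7.02,1,0.008
gap_kw,leg_gap,kruskal_wallis,no,S3,RightAntalgic,2.83,1,0.093
gap_kw,leg_gap,kruskal_wallis,no,S3,LeftAntalgic,1.19,1,0.276
gap_kw,leg_gap,kruskal_wallis,no,S3,All,33.32,4,0.000
gap_kw,leg_gap,kruskal_wallis,no,S4,Fast,44.59,1,0.000
gap_kw,leg_gap,kruskal_wallis,no,S4,Slow,34.44,1,0.000
gap_kw,leg_gap,kruskal_wallis,no,S4,RightAntalgic,50.03,1,0.000
gap_kw,leg_gap,kruskal_wallis,no,S4,LeftAntalgic,58.99,1,0.000
gap_kw,leg_gap,kruskal_wallis,no,S4,All,135.58,4,0.000
gap_kw_no_outliers,leg_gap,kruskal_wallis,yes,S1,Fast,10.70,1,0.001
gap_kw_no_outliers,leg_gap,kruskal_wallis,yes,S1,Slow,2.62,1,0.105
gap_kw_no_outliers,leg_gap,kruskal_wallis,yes,S1,RightAntalgic,16.12,1,0.000
gap_kw_no_outliers,leg_gap,kruskal_wallis,yes,S1,LeftAntalgic,9.13,1,0.003
gap_kw_no_outliers,leg_gap,kruskal_wallis,yes,S1,All,55.45,4,0.000
gap_kw_no_outliers,leg_gap,kruskal_wallis,yes,S2,Fast,3.22,1,0.073
gap_kw_no_outliers,leg_gap,kruskal_wallis,yes,S2,Slow,1.52,1,0.217
gap_kw_no_outliers,leg_gap,kruskal_wallis,yes,S2,RightAntalgic,50.93,1,0.000
gap_kw_no_outliers,leg_gap,kruskal_wallis,yes,S2,LeftAntalgic,23.10,1,0.000
gap_kw_no_outliers,leg_gap,kruskal_wallis,yes,S2,All,101.95,4,0.000
gap_kw_no_outliers,leg_gap,kruskal_wallis,yes,S3,Fast,5.03,1,0.025
gap_kw_no_outliers,leg_gap,kruskal_wallis,yes,S3,Slow,7.35,1,0.007
gap_kw_no_outliers,leg_gap,kruskal_wallis,yes,S3,RightAntalgic,2.98,1,0.084
gap_kw_no_outliers,leg_gap,kruskal_wallis,yes,S3,LeftAntalgic,1.63,1,0.202
gap_kw_no_outliers,leg_gap,kruskal_wallis,yes,S3,All,36.92,4,0.000
gap_kw_no_outliers,leg_gap,kruskal_wallis,yes,S4,Fast,44.83,1,0.000
gap_kw_no_outliers,leg_gap,kruskal_wallis,yes,S4,Slow,34.64,1,0.000
gap_kw_no_outliers,leg_gap,kruskal_wallis,yes,S4,RightAntalgic,49.97,1,0.000
gap_kw_no_outliers,leg_gap,kruskal_wallis,yes,S4,LeftAntalgic,59.23,1,0.000
gap_kw_no_outliers,leg_gap,kruskal_wallis,yes,S4,All,138.14,4,0.000
gap_levene,leg_gap,levene,no,S1,Fast,14.09,1,0.0003
gap_levene,leg_gap,levene,no,S1,Slow,7.28,1,0.009
gap_levene,leg_gap,levene,no,S1,RightAntalgic,8.04,1,0.006
gap_levene,leg_gap,levene,no,S1,LeftAntalgic,1.19,1,0.279
gap_levene,leg_gap,levene,no,S2,Fast,4.16,1,0.048
gap_levene,leg_gap,levene,no,S2,Slow,0.34,1,0.562
gap_levene,leg_gap,levene,no,S2,RightAntalgic,29.89,1,0.000
gap_levene,leg_gap,levene,no,S2,LeftAntalgic,16.79,1,0.0001
gap_levene,leg_gap,levene,no,S3,Fast,0.04,1,0.844
gap_levene,leg_gap,levene,no,S3,Slow,3.92,1,0.051
gap_levene,leg_gap,levene,no,S3,RightAntalgic,1.56,1,0.214
gap_levene,leg_gap,levene,no,S3,LeftAntalgic,5.01,1,0.028
gap_levene,leg_gap,levene,no,S4,Fast,29.31,1,0.000
gap_levene,leg_gap,levene,no,S4,Slow,22.56,1,0.000
gap_levene,leg_gap,levene,no,S4,RightAntalgic,33.73,1,0.000
gap_levene,leg_gap,levene,no,S4,LeftAntalgic,59.24,1,0.000
gap_levene_no_outliers,leg_gap,levene,yes,S1,Fast,14.37,1,0.0004
gap_levene_no_outliers,leg_gap,levene,yes,S1,Slow,7.42,1,0.008
gap_levene_no_outliers,leg_gap,levene,yes,S1,RightAntalgic,8.82,1,0.005
gap_levene_no_outliers,leg_gap,levene,yes,S1,LeftAntalgic,2.09,1,0.156
gap_levene_no_outliers,leg_gap,levene,yes,S2,Fast,6.80,1,0.011
gap_levene_no_outliers,leg_gap,levene,yes,S2,Slow,4.15,1,0.045
gap_levene_no_outliers,leg_gap,levene,yes,S2,RightAntalgic,49.57,1,0.000
gap_levene_no_outliers,leg_gap,levene,yes,S2,LeftAntalgic,16.57,1,0.000
gap_levene_no_outliers,leg_gap,levene,yes,S3,Fast,0.03,1,0.87
gap_levene_no_outliers,leg_gap,levene,yes,S3,Slow,4.67,1,0.033
gap_levene_no_outliers,leg_gap,levene,yes,S3,RightAntalgic,2.57,1,0.112
gap_levene_no_outliers,leg_gap,levene,yes,S3,LeftAntalgic,7.28,1,0.008
gap_levene_no_outliers,leg_gap,levene,yes,S4,Fast,35.84,1,0.000
gap_levene_no_outliers,leg_gap,levene,yes,S4,Slow,27.19,1,0.000
gap_levene_no_outliers,leg_gap,levene,yes,S4,RightAntalgic,38.99,1,0.000
gap_levene_no_outliers,leg_gap,levene,yes,S4,LeftAntalgic,78.45,1,0.000
cadence_kw,cadence,kruskal_wallis,no,S1,Fast,30.10,1,0.000
cadence_kw,cadence,kruskal_wallis,no,S1,Slow,45.60,1,0.000
cadence_kw,cadence,kruskal_wallis,no,S1,RightAntalgic,3.89,1,0.049
cadence_kw,cadence,kruskal_wallis,no,S1,LeftAntalgic,5.03,1,0.025
cadence_kw,cadence,kruskal_wallis,no,S2,Fast,53.20,1,0.000
cadence_kw,cadence,kruskal_wallis,no,S2,Slow,47.95,1,0.000
cadence_kw,cadence,kruskal_wallis,no,S2,RightAntalgic,5.16,1,0.023
cadence_kw,cadence,kruskal_wallis,no,S2,LeftAntalgic,10.11,1,0.000
cadence_kw,cadence,kruskal_wallis,no,S3,Fast,46.62,1,0.000
cadence_kw,cadence,kruskal_wallis,no,S3,Slow,67.32,1,0.000
cadence_kw,cadence,kruskal_wallis,no,S3,RightAntalgic,10.86,1,0.001
cadence_kw,cadence,kruskal_wallis,no,S3,LeftAntalgic,11.09,1,0.0009
cadence_kw,cadence,kruskal_wallis,no,S4,Fast,42.32,1,0.000
cadence_kw,cadence,kruskal_wallis,no,S4,Slow,41.57,1,0.000
cadence_kw,cadence,kruskal_wallis,no,S4,RightAntalgic,31.17,1,0.000
cadence_kw,cadence,kruskal_wallis,no,S4,LeftAntalgic,43.36,1,0.000
cadence_levene,cadence,levene,no,S1,Fast,0.53,1,0.487
cadence_levene,cadence,levene,no,S1,Slow,0.90,1,0.347
cadence_levene,cadence,levene,no,S1,RightAntalgic,0.47,1,0.496
cadence_levene,cadence,levene,no,S1,LeftAntalgic,5.48,1,0.023
cadence_levene,cadence,levene,no,S2,Fast,0.36,1,0.551
cadence_levene,cadence,levene,no,S2,Slow,0.48,1,0.402
cadence_levene,cadence,levene,no,S2,RightAntalgic,1.04,1,0.312
cadence_levene,cadence,levene,no,S2,LeftAntalgic,0.92,1,0.341
cadence_levene,cadence,levene,no,S3,Fast,0.41,1,0.524
cadence_levene,cadence,levene,no,S3,Slow,9.35,1,0.493
cadence_levene,cadence,levene,no,S3,RightAntalgic,0.09,1,0.763
cadence_levene,cadence,levene,no,S3,LeftAntalgic,0.89,1,0.345
cadence_levene,cadence,levene,no,S4,Fast,7.57,1,0.008
cadence_levene,cadence,levene,no,S4,Slow,6.69,1,0.0013
cadence_levene,cadence,levene,no,S4,RightAntalgic,3.33,1,0.073
cadence_levene,cadence,levene,no,S4,LeftAntalgic,0.65,1,0.424
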