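measure,subject,stride_type,n,mean,sd,iqr,max,min,skewness,kurtosis,normal
leg_gap,S1,Normal,37,1.53,0.046,0.057,1.61,1.44,-0.24,2.33,Y
leg_gap,S1,Fast,38,1.42,0.090,0.114,1.59,1.24,0.22,2.54,Y
leg_gap,S1,Slow,48,1.50,0.091,0.099,1.61,1.12,-1.60,5.61,N
leg_gap,S1,RightAntalgic,37,1.41,0.089,0.086,1.52,1.46,-1.09,3.43,N
leg_gap,S1,LeftAntalgic,40,1.55,0.040,0.061,1.29,1.14,-0.67,2.55,N
leg_gap,S2,Normal,44,1.58,0.017,0.017,1.61,1.50,-2.50,13.50,N
leg_gap,S2,Fast,38,1.59,0.023,0.025,1.61,1.52,-1.12,3.91,N
leg_gap,S2,Slow,44,1.58,0.016,0.025,1.61,1.53,-0.43,4.40,Y
leg_gap,S2,RightAntalgic,42,1.48,0.065,0.079,1.60,1.25,-1.01,5.64,Y
leg_gap,S2,LeftAntalgic,46,1.55,0.048,0.036,1.61,1.37,-1.60,5.86,N
leg_gap,S3,Normal,51,1.49,0.074,0.088,1.60,1.28,-0.68,3.08,Y
leg_gap,S3,Fast,41,1.47,0.072,0.093,1.62,1.29,-0.25,2.91,Y
leg_gap,S3,Slow,53,1.53,0.054,0.071,1.62,1.36,-0.83,3.68,Y
leg_gap,S3,RightAntalgic,50,1.48,0.063,0.071,1.60,1.25,-0.84,5.13,Y
leg_gap,S3,LeftAntalgic,49,1.51,0.050,0.064,1.61,1.38,-0.55,3.18,Y
leg_gap,S4,Normal,38,1.53,0.044,0.064,1.61,1.41,-0.46,3.26,Y
leg_gap,S4,Fast,32,1.60,0.012,0.013,1.62,1.57,-1.01,3.45,N
leg_gap,S4,Slow,34,1.59,0.016,0.018,1.61,1.55,-0.81,3.33,Y
leg_gap,S4,RightAntalgic,36,1.61,0.011,0.017,1.62,1.58,-0.89,3.07,N
leg_gap,S4,LeftAntalgic,41,1.62,0.005,0.005,1.63,1.60,-3.11,17.10,N
cadence,S1,Normal,29,122.22,2.06,3.13,125.92,117.42,-0.37,2.73,Y
cadence,S1,Fast,27,127.97,3.45,2.35,133.33,116.39,-2.07,7.73,N
cadence,S1,Slow,33,100.74,2.54,3.15,105.45,95.16,-0.49,2.78,Y
cadence,S1,RightAntalgic,30,121.15,2.32,2.68,125.66,116.73,0.25,2.47,Y
cadence,S1,LeftAntalgic,34,120.50,3.03,4.47,125.13,113.74,-0.59,2.39,N
cadence,S2,Normal,41,117.15,3.64,4.12,127.52,108.11,0.39,4.36,Y
cadence,S2,Fast,32,134.17,4.34,3.77,145.81,129.31,1.49,4.72,N
cadence,S2,Slow,43,110.33,2.97,3.63,121.09,104.26,0.50,5.61,N
cadence,S2,RightAntalgic,36,118.75,4.06,4.86,124.74,108.50,-0.82,3.29,Y
cadence,S2,LeftAntalgic,42,119.34,2.85,2.96,126.58,112.36,0.29,3.54,Y
cadence,S3,Normal,43,110.75,3.73,4.55,117.76,101.35,-0.67,3.24,N
cadence,S3,Fast,35,119.41,4.39,4.78,132.01,111.32,0.66,3.79,Y
cadence,S3,Slow,48,77.44,3.30,3.57,86.15,70.01,-0.24,3.33,Y
cadence,S3,RightAntalgic,44,108.44,4.14,4.59,120.48,99.50,0.48,4.52,Y
cadence,S3,LeftAntalgic,43,107.77,4.01,4.01,115.72,99.09,-0.14,2.36,Y
cadence,S4,Normal,32,118.40,2.93,4.40,123.33,111.63,-0.63,2.98,Y
cadence,S4,Fast,26,141.06,4.72,7.40,149.25,130.72,-0.24,2.43,Y
cadence,S4,Slow,28,105.53,4.95,7.07,115.16,97.56,0.10,2.27,Y
cadence,S4,RightAntalgic,29,125.10,4.00,6.14,132.01,115.72,-0.43,2.78,Y
cadence,S4,LeftAntalgic,35,125.26,2.53,2.98,129.31,119.28,-0.46,2.88,Y
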