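# Group-level distribution parameters of the two-timepoint cohort:
# per group (SCD n=38, AD n=24) and Braak composite ROI, the mean (SD) of
# baseline DVR, SUVr(80-100 min) and R1, the mean (SD) of their subject
# percentage changes, and the scan interval in years.
group,roi,n_subjects,dvr_base_mean,dvr_base_sd,pct_change_dvr_mean,pct_change_dvr_sd,suvr_base_mean,suvr_base_sd,pct_change_suvr_mean,pct_change_suvr_sd,r1_base_mean,r1_base_sd,pct_change_r1_mean,pct_change_r1_sd,interval_mean,interval_sd
SCD,BraakI_II,38,1.039,0.121,2.56,2.85,1.134,0.159,1.85,3.27,0.708,0.041,0.74,3.96,2.1,0.3
SCD,BraakIII_IV,38,1.045,0.075,2.82,2.54,1.102,0.103,2.47,2.64,0.836,0.036,0.79,2.75,2.1,0.3
SCD,BraakV_VI,38,1.042,0.057,2.33,2.77,1.076,0.077,2.17,3.29,0.926,0.043,0.47,2.67,2.1,0.3
AD,BraakI_II,24,1.277,0.146,3.48,4.16,1.426,0.192,3.25,5.26,0.713,0.047,-0.87,5.26,2.2,0.3
AD,BraakIII_IV,24,1.256,0.147,6.61,5.63,1.367,0.190,7.52,6.66,0.835,0.045,-1.62,3.71,2.2,0.3
AD,BraakV_VI,24,1.284,0.222,7.25,6.85,1.382,0.281,8.21,8.03,0.904,0.051,-2.28,3.67,2.2,0.3
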