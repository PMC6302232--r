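disease,messages,correction_factor_pct,corrected,users,nonmedical
breast cancer,39169,100,39156,19960,NA
leukemia,9129,95.1,8682,5855,NA
lung cancer,5745,92.6,5317,3719,NA
lymphoma,5276,93.4,4927,2758,NA
ovarian cancer,3063,99.9,3060,1212,NA
pancreatic cancer,3231,100,3231,1189,NA
prostate cancer,4487,100,4487,2311,NA
skin cancer,7866,99.9,7859,4048,NA
asthma,18082,92.6,16742,10185,NA
chronic obstructive pulmonary disease,2137,77.1,1648,726,NA
diabetes,41615,96.6,40217,16321,NA
heart disease,14740,92.7,13669,7992,NA
hypertension,18404,93.7,17245,12203,NA
stroke,53858,15.1,8141,34298,45716
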