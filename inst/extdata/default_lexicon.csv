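disease,keyword
breast cancer,breast cancer
breast cancer,mammogram
breast cancer,mastectomy
breast cancer,brca
leukemia,leukemia
leukemia,leukaemia
lung cancer,lung cancer
lung cancer,lung tumor
lymphoma,lymphoma
lymphoma,hodgkins
lymphoma,non hodgkins
ovarian cancer,ovarian cancer
ovarian cancer,ovarian tumor
pancreatic cancer,pancreatic cancer
pancreatic cancer,cancer of the pancreas
prostate cancer,prostate cancer
prostate cancer,psa test
skin cancer,skin cancer
skin cancer,melanoma
skin cancer,basal cell carcinoma
asthma,asthma
asthma,inhaler
asthma,asthmatic
chronic obstructive pulmonary disease,copd
chronic obstructive pulmonary disease,emphysema
chronic obstructive pulmonary disease,chronic bronchitis
diabetes,diabetes
diabetes,diabetic
diabetes,insulin
diabetes,blood sugar
heart disease,heart disease
heart disease,heart attack
heart disease,heart failure
heart disease,angina
heart disease,coronary
hypertension,hypertension
hypertension,high blood pressure
hypertension,blood pressure
stroke,stroke
stroke,mini stroke
stroke,transient ischemic attack
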