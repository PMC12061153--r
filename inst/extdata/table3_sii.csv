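study_id,pub_year,predictor,outcome,p_reported,or,ci_low,ci_high,window_start,window_end,variable_key,cohort,journal,affiliation_country
39052624,2024,SII,Liver injury,,,,,2017,2020,LBXSATSI,,,
39312354,2024,SII,Hearing loss,,,,,2005,2018,AUX,,,
38974989,2024,SII,Diabetes,,,,,2003,2018,DIQ,,,
38822015,2024,SII,Overactive bladder,,,,,2005,2018,KIQ480,,,
39069464,2024,SII,Obesity,,,,,2011,2018,BMXBMI,,,
39076553,2024,SII,Stroke,,,,,1999,2020,MCQ160F,,,
38988356,2024,SII,Asthma,,,,,2009,2018,MCQ010,,,
39239395,2024,SII,Serum neurofilament light chain,,,,,2013,2014,SSSNFL,,,
39267962,2024,SII,Atopic dermatitis,,,,,2001,2006,DED061,,,
36904176,2023,SII,Hyperlipidemia,,,,,2015,2020,TCHOL,,,
37883981,2023,SII,Serum ferritin levels,,,,,2015,2018,LBXFER,,,
38027115,2023,SII,Diabetes,,,,,2017,2020,DIQ,,,
38076255,2023,SII,Chronic obstructive pulmonary disease (COPD),,,,,2013,2020,MCQ160G,,,
36895572,2023,SII,Kidney stones,,,,,2007,2018,KIQ026,,,
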