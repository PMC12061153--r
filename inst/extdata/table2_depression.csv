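study_id,pub_year,predictor,outcome,p_reported,or,ci_low,ci_high,window_start,window_end,variable_key,cohort,journal,affiliation_country
39277033,2024,Serum neurofilament light chains,depression,0.039,,,,,,,,,
39355374,2024,Blood pressure,depression,0.044,,,,,,,,,
38869164,2024,Life's Essential 8,depression,<0.001,,,,,,,,,
39121312,2024,Triglyceride-glucose index,depression,<0.001,,,,,,,,,
38970091,2024,Adherence to Mediterranean diet,depression,0.039,,,,,,,,,
38355455,2024,Geriatric nutritional risk index,depression,<0.001,,,,,,,,,
38642902,2024,Overactive bladder,depression,<0.001,,,,,,,,,
39029685,2024,Muscle mass,depression,0.008,,,,,,,,,
38710330,2024,Dietary vitamin C intake,depression,<0.001,,,,,,,,,
38944294,2024,Immune-inflammation-based prognostic index,depression,<0.001,,,,,,,,,
38579547,2024,Physical activity,depression,0.032,,,,,,,,,
39044344,2024,Lipid accumulation products,depression,0.031,,,,,,,,,
38154580,2024,Ethylene oxide levels,depression,0.021,,,,,,,,,
38220117,2024,Weight-Adjusted Waist Index,depression,0.008,,,,,,,,,
38910137,2024,Blood cadmium,depression,<0.001,,,,,,,,,
37838268,2024,Non-HDL cholesterol to HDL cholesterol ratio (NHHR),depression,0.031,,,,,,,,,
37775007,2023,Per- and polyfluoroalkyl substances (PFAS),depression,<0.001,,,,,,,,,
39227001,2023,Non-high-density lipoprotein cholesterol,depression,0.023,,,,,,,,,
37474898,2023,Dietary anthocyanidins intake,depression,0.020,,,,,,,,,
37236270,2023,Serum alpha-Klotho,depression,0.022,,,,,,,,,
37447273,2023,Serum Vitamin D,depression,0.032,,,,,,,,,
36462606,2023,Dietary Inflammatory Index (DII),depression,<0.001,,,,,,,,,
37340352,2023,Serum albumin,depression,0.037,,,,,,,,,
36265728,2023,Organophosphorus pesticide exposure,depression,0.040,,,,,,,,,
36008859,2022,Physical activity,depression,<0.001,,,,,,,,,
33292309,2020,Ovariectomy-reduced hormones,depression,<0.001,,,,,,,,,
28395506,2017,Inflammatory bowel disease,depression,0.002,,,,,,,,,
24636212,2014,Poor dental health,depression,<0.001,,,,,,,,,
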