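exposure,disease,rr,rr_low,rr_high,increment_g,source
fruit,coronary_heart_disease,0.93,0.89,0.96,80,Dauchet et al.
fruit,stroke,0.89,0.85,0.93,80,Dauchet et al.
fruit,oral_cancer,0.72,0.59,0.87,100,WCRF/Marmot et al.
fruit,oesophageal_cancer,0.56,0.42,0.74,100,WCRF/Marmot et al.
fruit,lung_cancer,0.94,0.90,0.97,80,WCRF/Marmot et al.
fruit,stomach_cancer,0.67,0.59,0.76,100,WCRF/Marmot et al.
vegetable,coronary_heart_disease,0.89,0.83,0.95,80,Dauchet et al.
vegetable,stroke,0.97,0.92,1.02,80,Dauchet et al.
vegetable,oral_cancer,0.72,0.63,0.82,50,WCRF/Marmot et al.
vegetable,oesophageal_cancer,0.87,0.72,1.05,50,WCRF/Marmot et al.
vegetable,stomach_cancer,0.70,0.62,0.79,100,WCRF/Marmot et al.
red_meat,colorectal_cancer,1.29,1.04,1.60,100,WCRF/Marmot et al.
red_meat,type2_diabetes,1.19,1.04,1.37,100,Pan et al.
red_meat,stroke,1.21,1.10,1.33,100,Micha et al.
processed_meat,colorectal_cancer,1.21,1.04,1.42,50,WCRF/Marmot et al.
processed_meat,type2_diabetes,1.51,1.25,1.83,100,Pan et al.
processed_meat,coronary_heart_disease,1.37,1.11,1.68,50,Micha et al.
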