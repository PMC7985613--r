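list_name,kind,code
depression,morbidity,DEP1
depression,morbidity,DEP2
anxiety,morbidity,ANX1
diabetes,morbidity,DM1
asthma,morbidity,AST1
copd,morbidity,COPD1
smoking,morbidity,SMOK1
heart_failure,morbidity,HF1
oral_corticosteroid,prescription,OCS1
antibiotic,prescription,ABX1
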