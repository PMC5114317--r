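"study","arm","cmax_obs","cmax_obs_flag","cmax_pred","auc_obs","auc_pred"
"fluoxetine","T","2","",2.3,"24.6",15.3
"fluoxetine","T+I","1.4","",2.3,"14.2",15.3
"erythromycin_cr15","T","<5","",2.71,NA,NA
"erythromycin_cr15","T+I","20.3","for 3 of 9 subjects",9.74,NA,NA
"fluconazole","T","<5","",2.48,NA,NA
"fluconazole","T+I","<5","",4.11,NA,NA
"itraconazole","T","7.63","for 3 of 6 subjects",4.9,NA,NA
"itraconazole","T+I","14.97","for 3 of 6 subjects",14.6,NA,NA
"ketoconazole","T","7","for 1 of 6 subjects",2.23,NA,NA
"ketoconazole","T+I","49.3","graph estimate for 5 of 6 subjects",19.67,NA,NA
"clarithromycin","T","<5","",9,NA,NA
"clarithromycin","T+I","2.39","",7.03,NA,NA
"erythromycin_cr19","T","<5","",2.47,NA,NA
"erythromycin_cr19","T+I","7.6","for 3 of 6 subjects",8.98,NA,NA
"paroxetine","T","3.68","",2.31,"30.8",20.5
"paroxetine","T+I","3.64","",2.48,"30",27.5
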