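"study","arm","observed","pred_sum","pred_bliss","pred_loewe","delta_only"
"fluoxetine","BL",372.4,396,396,396,0
"fluoxetine","T",374.9,398.5,398.5,398.5,0
"fluoxetine","I",NA,400.9,400.9,400.9,0
"fluoxetine","T+I",379,401.6,400.8,400.2,0
"erythromycin_cr15","BL",NA,392.8,392.8,392.8,1
"erythromycin_cr15","T",8,398.5,398.5,398.5,1
"erythromycin_cr15","I",21,403.7,403.7,403.7,1
"erythromycin_cr15","T+I",39,418.2,413.6,411.4,1
"fluconazole","BL",398.5,395.2,395.2,395.2,0
"fluconazole","T",398.4,401.3,401.3,401.3,0
"fluconazole","I",NA,414.3,414.3,414.3,0
"fluconazole","T+I",411,422.6,418.6,416.8,0
"itraconazole","BL",376,430.5,430.5,430.5,0
"itraconazole","T",390,438,438,438,0
"itraconazole","I",NA,486.9,486.9,486.9,0
"itraconazole","T+I",417,452.2,448.9,447.3,0
"ketoconazole","BL",408,394.5,394.5,394.5,0
"ketoconazole","T",416,395,395,395,0
"ketoconazole","I",NA,415.4,415.4,415.4,0
"ketoconazole","T+I",490,439,427.9,423.6,0
"clarithromycin","BL",409,395.5,395.5,395.5,0
"clarithromycin","T",410,401.4,401.4,401.4,0
"clarithromycin","I",407,393.9,393.9,393.9,0
"clarithromycin","T+I",430,404.4,403.8,402.7,0
"erythromycin_cr19","BL",394,397.5,397.5,397.5,0
"erythromycin_cr19","T",408,403.7,403.7,403.7,0
"erythromycin_cr19","I",409,405.8,405.8,405.8,0
"erythromycin_cr19","T+I",428,420.1,415.6,413.5,0
"paroxetine","BL",381,392,392,392,0
"paroxetine","T",387,394.5,394.5,394.5,0
"paroxetine","I",NA,393.5,393.5,393.5,0
"paroxetine","T+I",386,396.6,393.6,396.8,0
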