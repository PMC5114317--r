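"study","model","distance"
"fluoxetine","sum",1.49
"fluoxetine","bliss",2.59
"fluoxetine","loewe",3.34
"erythromycin_cr15","sum",18.38
"erythromycin_cr15","bliss",22.75
"erythromycin_cr15","loewe",25.13
"fluconazole","sum",31.28
"fluconazole","bliss",26.02
"fluconazole","loewe",23.65
"itraconazole","sum",24.05
"itraconazole","bliss",28.5
"itraconazole","loewe",30.68
"ketoconazole","sum",48.61
"ketoconazole","bliss",64.03
"ketoconazole","loewe",70.14
"clarithromycin","sum",21.43
"clarithromycin","bliss",22.96
"clarithromycin","loewe",23.79
"erythromycin_cr19","sum",14.27
"erythromycin_cr19","bliss",19.46
"erythromycin_cr19","loewe",22.17
"paroxetine","sum",4.69
"paroxetine","bliss",4.86
"paroxetine","loewe",4.78
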