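"study","pct_cases"
"fluoxetine",0.1
"erythromycin_cr15",2.8
"fluconazole",3.8
"itraconazole",2.3
"ketoconazole",5.6
"clarithromycin",0.2
"erythromycin_cr19",3.3
"paroxetine",0
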