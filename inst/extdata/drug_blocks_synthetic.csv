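"drug","channel","ic50_uM","hill_n"
"terfenadine","IKr",0.06,1
"terfenadine","INa",3,1
"terfenadine","ICaL",5,1
"ketoconazole","IKr",2,1
"ketoconazole","ICaL",10,1
"erythromycin","IKr",20,1
"clarithromycin","IKr",15,1
"fluconazole","IKr",50,1
"fluoxetine","IKr",1.5,1
"fluoxetine","ICaL",4,1
"itraconazole","IKr",5,1
"paroxetine","IKr",2,1
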