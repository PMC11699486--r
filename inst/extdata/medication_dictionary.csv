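name,class,source
aspirin,aspirin,dictionary
ascard,aspirin,dictionary
disprin,aspirin,dictionary
loprin,aspirin,dictionary
atorvastatin,statin,dictionary
rosuvastatin,statin,dictionary
simvastatin,statin,dictionary
lipitor,statin,dictionary
lipiget,statin,dictionary
crestor,statin,dictionary
clopidogrel,clopidogrel,dictionary
plavix,clopidogrel,dictionary
lowplat,clopidogrel,dictionary
noclot,clopidogrel,dictionary
metoprolol,beta_blocker,dictionary
carvedilol,beta_blocker,dictionary
bisoprolol,beta_blocker,dictionary
atenolol,beta_blocker,dictionary
inderal,beta_blocker,dictionary
concor,beta_blocker,dictionary
metformin,antidiabetic,dictionary
glucophage,antidiabetic,dictionary
sitagliptin,antidiabetic,dictionary
gliclazide,antidiabetic,dictionary
insulin,antidiabetic,dictionary
enalapril,ace_inhibitor,dictionary
lisinopril,ace_inhibitor,dictionary
ramipril,ace_inhibitor,dictionary
captopril,ace_inhibitor,dictionary
renitec,ace_inhibitor,dictionary
zestril,ace_inhibitor,dictionary
losartan,arb,dictionary
valsartan,arb,dictionary
telmisartan,arb,dictionary
eziday,arb,dictionary
telsan,arb,dictionary
cozaar,arb,dictionary
coplavix,aspirin_clopidogrel_combo,dictionary
duoplavin,aspirin_clopidogrel_combo,dictionary
ticagrelor,ticagrelor,dictionary
brilinta,ticagrelor,dictionary
brilique,ticagrelor,dictionary
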