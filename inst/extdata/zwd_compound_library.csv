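id,name,herb,class,ion_mode,mz,response_factor
hypaconitine,Hypaconitine,Fuzi,DIESTER_TOXIC,pos,616,1.0
benzoylhypaconitine,Benzoylhypaconitine,Fuzi,MONOESTER_ACTIVE,pos,574,1.0
benzoylmesaconine,Benzoylmesaconine,Fuzi,MONOESTER_ACTIVE,pos,590,1.0
benzoylaconitine,Benzoylaconitine,Fuzi,MONOESTER_ACTIVE,pos,604,1.0
mesaconine,Mesaconine,Fuzi,AMINOALCOHOL,pos,486,1.0
hypaconine,Hypaconine,Fuzi,AMINOALCOHOL,pos,470,1.0
aconine,Aconine,Fuzi,AMINOALCOHOL,pos,500,1.0
songorine,Songorine,Fuzi,STABLE_DISSOLUTION_ONLY,pos,358,0.8
fuzitine,Fuzitine,Fuzi,STABLE_DISSOLUTION_ONLY,pos,454,1.0
shogaol_6,6-Shogaol,Shengjiang,CONVERSION_PRODUCT,pos,277,1.0
zingerone,Zingerone,Shengjiang,CONVERSION_PRODUCT,pos,195,1.0
atractylenolide_1,Atractylenolide I,Baizhu,STABLE_DISSOLUTION_ONLY,pos,231,1.25
atractylenolide_3,Atractylenolide III,Baizhu,STABLE_DISSOLUTION_ONLY,pos,249,1.0
paeoniflorin,Paeoniflorin,Baishao,DECLINING_GLYCOSIDE,neg,525,1.0
paeoniflorin_sulfonate,Paeoniflorin sulfonate,Baishao,DECLINING_GLYCOSIDE,neg,543,1.0
pentagalloylglucose,"1,2,3,4,6-Pentagalloylglucose",Baishao,INTERMEDIATE_BIPHASIC,neg,939,1.0
gallic_acid,Gallic acid,Baishao,HYDROLYSIS_PRODUCT_RISING,neg,169,1.0
ellagic_acid,Ellagic acid,Baishao,HYDROLYSIS_PRODUCT_RISING,neg,301,1.0
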