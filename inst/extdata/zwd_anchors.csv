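compound_id,system,target,time_min,intensity
hypaconitine,SINGLE,peak,NA,7360
hypaconitine,SINGLE,end,240,3480
hypaconitine,CO,peak,NA,4490
benzoylhypaconitine,SINGLE,start,0,36600
benzoylhypaconitine,SINGLE,end,240,9930
benzoylhypaconitine,CO,start,0,22700
benzoylhypaconitine,CO,end,240,24500
benzoylaconitine,SINGLE,start,0,39200
benzoylaconitine,SINGLE,end,240,7300
benzoylaconitine,CO,start,0,25800
benzoylaconitine,CO,end,240,23300
benzoylmesaconine,SINGLE,start,0,284000
benzoylmesaconine,SINGLE,end,240,28600
benzoylmesaconine,CO,start,0,183000
benzoylmesaconine,CO,end,240,139000
mesaconine,SINGLE,at_time,30,21800
mesaconine,SINGLE,peak,NA,146000
pentagalloylglucose,SINGLE,at_time,100,1920
pentagalloylglucose,SINGLE,at_time,180,8620
pentagalloylglucose,SINGLE,at_time,225,6800
gallic_acid,SINGLE,end,240,37900
gallic_acid,CO,end,240,10800
ellagic_acid,SINGLE,end,240,8150
ellagic_acid,CO,end,240,2090
shogaol_6,SINGLE,start,0,3420
shogaol_6,SINGLE,end,240,10300
zingerone,SINGLE,start,0,3320
zingerone,SINGLE,end,240,22600
zingerone,CO,start,0,1870
zingerone,CO,end,240,6780
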