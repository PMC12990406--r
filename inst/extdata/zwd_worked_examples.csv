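label,compound_id,system,convention,reference,final,printed_pct
hypaconitine_single,hypaconitine,SINGLE,peak,7360,3480,-52.7
benzoylhypaconitine_single,benzoylhypaconitine,SINGLE,initial,36600,9930,-72.9
benzoylaconitine_single,benzoylaconitine,SINGLE,initial,39200,7300,-81.4
benzoylmesaconine_single,benzoylmesaconine,SINGLE,initial,284000,28600,-89.9
benzoylhypaconitine_co,benzoylhypaconitine,CO,initial,22700,24500,7.9
benzoylaconitine_co,benzoylaconitine,CO,initial,25800,23300,-9.7
benzoylmesaconine_co,benzoylmesaconine,CO,initial,183000,139000,-24.0
mesaconine_single,mesaconine,SINGLE,point30_to_peak,21800,146000,570
shogaol_6_single,shogaol_6,SINGLE,initial,3420,10300,201.2
zingerone_single,zingerone,SINGLE,initial,3320,22600,580.7
zingerone_co,zingerone,CO,initial,1870,6780,262.6
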