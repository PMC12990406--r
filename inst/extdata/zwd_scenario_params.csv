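compound_id,system,observe,rates,init,dip_depth,dip_center,dip_width
hypaconitine,SINGLE,2,0.08;0.00394929411797,7309.31855411;1289.87974484,NA,NA,NA
hypaconitine,CO,2,0.08;0.0107174796828,5199.63851165;917.583266762,NA,NA,NA
benzoylhypaconitine,SINGLE,3,0.08;0.01;0.0062817100186,4250;750;36600,NA,NA,NA
benzoylmesaconine,SINGLE,3,0.08;0.01;0.01027616016,17000;3000;284000,NA,NA,NA
benzoylaconitine,SINGLE,3,0.08;0.01;0.00775843792567,3400;600;39200,NA,NA,NA
benzoylhypaconitine,CO,3,0.08;0.015;0.0005,4177.21902578;737.156298667;22700,NA,NA,NA
benzoylmesaconine,CO,3,0.08;0.0140841760476;0.00291361500463,68541.3899124;12095.5393963;183000,NA,NA,NA
benzoylaconitine,CO,3,0.08;0.015;0.000834687718718,2210;390;25800,NA,NA,NA
mesaconine,SINGLE,3,0.08;0.000997405518679;0.00130688861857,685110.068891;120901.776863;6145.28650657,NA,NA,NA
mesaconine,CO,3,0.08;0.000997405518679;0.00130688861857,685110.068891;120901.776863;6145.28650657,NA,NA,NA
hypaconine,SINGLE,3,0.08;0.00685630387136;0.00166196090244,53222.4725608;9392.20104013;1193.02532105,NA,NA,NA
hypaconine,CO,3,0.08;0.00685630387136;0.00166196090244,53222.4725608;9392.20104013;1193.02532105,NA,NA,NA
aconine,SINGLE,3,0.08;0.00732395247917;0.00241205219599,46689.731873;8239.36444818;795.570345655,NA,NA,NA
aconine,CO,3,0.08;0.00732395247917;0.00241205219599,46689.731873;8239.36444818;795.570345655,0.22,75,18
songorine,SINGLE,2,0.09;0,12218.75;2156.25,NA,NA,NA
songorine,CO,2,0.09;0,12218.75;2156.25,NA,NA,NA
fuzitine,SINGLE,2,0.07;0,5355;945,NA,NA,NA
fuzitine,CO,2,0.07;0,5355;945,NA,NA,NA
atractylenolide_1,SINGLE,2,0.1;0,3536;624,NA,NA,NA
atractylenolide_1,CO,2,0.1;0,3536;624,NA,NA,NA
atractylenolide_3,SINGLE,2,0.085;0,6630;1170,NA,NA,NA
atractylenolide_3,CO,2,0.085;0,6630;1170,NA,NA,NA
zingerone,SINGLE,3,0.08;0.012;0,17518.9343997;3091.57665878;3320,NA,NA,NA
zingerone,CO,3,0.08;0.006;0,5588.93429149;986.282522027;1870,NA,NA,NA
shogaol_6,SINGLE,3,0.08;0.012;0,6251.56995177;1103.21822678;3420,NA,NA,NA
shogaol_6,CO,3,0.08;0.005;0,1990.53708085;351.271249561;3100,NA,NA,NA
paeoniflorin,SINGLE,2,0.09;0,42500;7500,NA,NA,NA
paeoniflorin_sulfonate,SINGLE,2,0.08;0,17850;3150,NA,NA,NA
paeoniflorin,CO,2,0.08;0.00367001354986,49259.6094541;8692.87225661,NA,NA,NA
paeoniflorin_sulfonate,CO,2,0.08;0.00196127063293,19587.5911801;3456.63373767,NA,NA,NA
pentagalloylglucose,SINGLE,12,0.0646253720242;0.0646253720242;0.0646253720242;0.0646253720242;0.0646253720242;0.0646253720242;0.0646253720242;0.0646253720242;0.0646253720242;0.0646253720242;0.128616531031;0.0238285320703,30773.3371355;0;0;0;0;0;0;0;0;0;0;50,NA,NA,NA
pentagalloylglucose,CO,12,0.0601015959825;0.0601015959825;0.0601015959825;0.0601015959825;0.0601015959825;0.0601015959825;0.0601015959825;0.0601015959825;0.0601015959825;0.0601015959825;0.119613373859;0.0221605348254,23080.0028516;0;0;0;0;0;0;0;0;0;0;40,NA,NA,NA
gallic_acid,SINGLE,3,0.08;0.009;0,35471.5223146;6259.68040846;1500,NA,NA,NA
gallic_acid,CO,3,0.08;0.009;0,9744.9237128;1719.69241991;800,NA,NA,NA
ellagic_acid,SINGLE,3,0.08;0.009;0,7552.31587742;1332.76162543;400,NA,NA,NA
ellagic_acid,CO,3,0.08;0.009;0,1841.79058172;325.021867362;200,NA,NA,NA
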