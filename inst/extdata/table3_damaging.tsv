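snp_id	sift_label_printed	sift_score	polyphen_label_printed	polyphen_score	protein_change	region
rs372875744	Damaging	0.03	Probably damaging	0.993	N125H	Helix B
rs535433995	Damaging	0.01	Probably damaging	0.975	H177R	Helix D
rs151249652	Damaging	0.01	Probably damaging	0.984	E194C	Beta sheet 3-1
rs536125410	Damaging	0	Probably damaging	0.982	L253S	Loop between helix F''/G, surface
rs141009880	Damaging	0.01	Possibly damaging	0.892	I274T	Helix G
rs140702410	Damaging	0	Probably damaging	0.969	R277L	Helix G
rs140118347	Damaging	0.02	Possibly damaging	0.799	A334S	Helix I
rs554366054	Damaging	0.02	Probably damaging	1	L417R	Loop between helix K' and meander, surface
rs138109473	Damaging	0	Probably damaging	0.974	R431H	Meander
rs542915180	Damaging	0	Probably damaging	0.999	R454H	Cys pocket
rs563098505	Damaging	0	Probably damaging	0.98	Y462D	Helix L, next to cys pocket
rs553164028	damaging	0	Probably damaging	0.997	R507K	C-terminal of the protein
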