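snp_id	protein_change	polyphen_label_printed	polyphen_score	sift_label_printed	sift_score	region	note
rs368261783	Y137C	Possibly damaging	0.497	damaging	0	SRS1	
rs750743669	S138N	Benign	0.262	damaging	0.04	SRS1	
rs758553106	R139C	Probably damaging	0.946	damaging	0.03	SRS1	
rs140356336	R139H	Benign	0.029	tolerated	0.65	SRS1	
COSM5500428	V144A	Probably damaging	0.994	tolerated	0.29	SRS1	
rs312262912	Y151D	Probably damaging	0.962	damaging	0	SRS1	
rs371492794	D152G	Probably damaging	0.988	damaging	0.01	SRS1	
COSM1202901 rs755026542	D152N	Probably damaging	0.985	damaging	0.01	SRS1	
rs776271983	A172V	Benign	0.101	tolerated	0.22	POR interaction	
/	L232P	Probably damaging	0.995	damaging	0	SRS2	
COSM353554	Y233*					SRS2	Unknown
COSM2863985	W245S	Probably damaging	0.981	damaging	0.01	Azole interaction	
rs753673809	W245Ter					Azole interaction	No protein
COSM1579448	W250S	Probably damaging	0.999	damaging	0.02	Azole interaction	
rs200921006 COSM3663398	R258C	Probably damaging	0.999	damaging	0	SRS3	
rs765961879 COSM1202902	R258H	Benign	0.93	damaging	0	SRS3	
rs765961879	R258L	Benign	0.168	damaging	0.01	SRS3	
rs745413412	H320P	Possibly damaging	0.899	damaging	0	SRS4	
rs377725460	T325A	Benign	0.359	damaging	0.01	SRS4	
rs760669078	P381T	Probably damaging	0.99	tolerated	0.08	SRS5	
rs150090274	I383V	Benign	0.024	damaging	0.05	SRS5	
rs150090274	I383L	Benign	0.143	tolerated	0.14	SRS5	
COSM3698597	M384I	Probably damaging	0.93	tolerated	0.34	SRS5	
rs759341868	I385F	Benign	0.075	damaging	0.01	SRS5	
rs773893086	M386V	Benign	0.376	tolerated	0.12	SRS5	
rs532896478	M386I	Benign	0.044	tolerated	1	SRS5	
rs765119371	M387I	Possibly damaging	0.758	damaging	0.05	SRS5	
COSM5986705	M387delM					SRS5	Unknown
rs748782320	R388Ter					SRS5	No protein
rs528934873	R452H	Benign	0.082	damaging	0.04	POR interaction	
rs779786966	R452C	Benign	0.166	damaging	0	POR interaction	
rs768113032	T492A	Benign	0.117	tolerated	0.15	SRS6	
rs749633381	M493V	Possibly damaging	0.545	damaging	0.02	SRS6	
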