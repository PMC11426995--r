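site_id	molecule	position_local	position_human	nucleotide	guide_snords
SSU-A40	SSU	40	40	A	
SSU-C57	SSU	57	57	C	
SSU-G74	SSU	74	74	G	
SSU-U91	SSU	91	91	U	
SSU-U116	SSU	116	116	U	
SSU-U121	SSU	121	121	U	SNORD23
SSU-A142	SSU	142	142	A	
SSU-C159	SSU	159	159	C	
SSU-G176	SSU	176	176	G	
SSU-U193	SSU	193	193	U	
SSU-A210	SSU	210	210	A	
SSU-C227	SSU	227	227	C	
SSU-G244	SSU	244	244	G	
SSU-U261	SSU	261	261	U	
SSU-A278	SSU	278	278	A	
SSU-C295	SSU	295	295	C	
SSU-G312	SSU	312	312	G	
SSU-U329	SSU	329	329	U	
SSU-U354	SSU	354	354	U	SNORD89
SSU-A380	SSU	380	380	A	
SSU-C397	SSU	397	397	C	
SSU-G414	SSU	414	414	G	
SSU-U428	SSU	428	428	U	
SSU-G436	SSU	436	436	G	SNORD14e
SSU-U465	SSU	465	465	U	
SSU-A482	SSU	482	482	A	
SSU-C499	SSU	499	499	C	
SSU-A512	SSU	512	512	A	
SSU-G533	SSU	533	533	G	
SSU-U550	SSU	550	550	U	
SSU-A567	SSU	567	567	A	
SSU-C584	SSU	584	584	C	
SSU-G601	SSU	601	601	G	
SSU-G618	SSU	618	618	G	
SSU-U635	SSU	635	635	U	
SSU-A652	SSU	652	652	A	
SSU-C669	SSU	669	669	C	
SSU-C797	SSU	797	797	C	
SSU-G867	SSU	867	867	G	SNORD37
SSU-C1272	SSU	1272	1272	C	SNORD66
SSU-U1326	SSU	1326	1326	U	
SSU-U1442	SSU	1442	1442	U	
SSU-G1447	SSU	1447	1447	G	
SSU-U1804	SSU	1804	1804	U	SNORD59a
5.8S-U14	5.8S	14	14	U	SNORD83b
5.8S-G75	5.8S	75	75	G	
LSU-A40	LSU	40	40	A	
LSU-C57	LSU	57	57	C	
LSU-G74	LSU	74	74	G	
LSU-U91	LSU	91	91	U	
LSU-A108	LSU	108	108	A	
LSU-C125	LSU	125	125	C	
LSU-G142	LSU	142	142	G	
LSU-U159	LSU	159	159	U	
LSU-A176	LSU	176	176	A	
LSU-C193	LSU	193	193	C	
LSU-G210	LSU	210	210	G	
LSU-U227	LSU	227	227	U	
LSU-A244	LSU	244	244	A	
LSU-C261	LSU	261	261	C	
LSU-G278	LSU	278	278	G	
LSU-U295	LSU	295	295	U	
LSU-A312	LSU	312	312	A	
LSU-C329	LSU	329	329	C	
LSU-G346	LSU	346	346	G	
LSU-U363	LSU	363	363	U	
LSU-A380	LSU	380	380	A	
LSU-C397	LSU	397	397	C	
LSU-G414	LSU	414	414	G	
LSU-U431	LSU	431	431	U	
LSU-A448	LSU	448	448	A	
LSU-C465	LSU	465	465	C	
LSU-G482	LSU	482	482	G	
LSU-U499	LSU	499	499	U	
LSU-A516	LSU	516	516	A	
LSU-C533	LSU	533	533	C	
LSU-G550	LSU	550	550	G	
LSU-U567	LSU	567	567	U	
LSU-A584	LSU	584	584	A	
LSU-C601	LSU	601	601	C	
LSU-G618	LSU	618	618	G	
LSU-U635	LSU	635	635	U	
LSU-A652	LSU	652	652	A	
LSU-C669	LSU	669	669	C	
LSU-G686	LSU	686	686	G	
LSU-U703	LSU	703	703	U	
LSU-A720	LSU	720	720	A	
LSU-C737	LSU	737	737	C	
LSU-G754	LSU	754	754	G	
LSU-U771	LSU	771	771	U	
LSU-A788	LSU	788	788	A	
LSU-C805	LSU	805	805	C	
LSU-G822	LSU	822	822	G	
LSU-G1303	LSU	1303	1303	G	SNORD60
LSU-A2388	LSU	2388	2388	A	
LSU-2402	LSU	2402	2402	U	
LSU-G2411	LSU	2411	2411	G	
LSU-C2848	LSU	2848	2848	C	
LSU-C3680	LSU	3680	3680	C	
LSU-A3804	LSU	3804	3804	A	
LSU-C3848	LSU	3848	3848	C	
LSU-G4020	LSU	4020	4020	G	
LSU-U4276	LSU	4276	4276	U	
LSU-G4362	LSU	4362	4362	G	
LSU-A4541	LSU	4541	4541	A	SNORD67
LSU-G4588	LSU	4588	4588	G	
LSU-G4593	LSU	4593	4593	G	SNORD78
LSU-G4607	LSU	4607	4607	G	
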