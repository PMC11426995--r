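site_id	category
SSU-U354	sharp_decrease
SSU-G436	sharp_decrease
SSU-G867	sharp_decrease
SSU-C1272	sharp_decrease
SSU-G1447	sharp_decrease
LSU-G4020	sharp_decrease
5.8S-U14	sharp_decrease
SSU-U116	slight_decrease
SSU-U121	slight_decrease
SSU-U428	slight_decrease
SSU-A512	slight_decrease
SSU-G601	slight_decrease
SSU-C797	slight_decrease
SSU-U1326	slight_decrease
SSU-U1442	slight_decrease
SSU-U1804	slight_decrease
LSU-G1303	slight_decrease
LSU-A2388	slight_decrease
LSU-2402	slight_decrease
LSU-G2411	slight_decrease
LSU-C2848	slight_decrease
LSU-C3680	slight_decrease
LSU-A3804	slight_decrease
LSU-C3848	slight_decrease
LSU-U4276	slight_decrease
LSU-G4362	slight_decrease
LSU-A4541	slight_decrease
LSU-G4588	slight_decrease
LSU-G4607	slight_decrease
LSU-G4593	gain_from_nonmethylation
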