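snord	site_id	host_gene
SNORD14e	SSU-G436	unknown
SNORD23	SSU-U121	unknown
SNORD37	SSU-G867	unknown
SNORD59a	SSU-U1804	unknown
SNORD60	LSU-G1303	unknown
SNORD66	SSU-C1272	unknown
SNORD67	LSU-A4541	unknown
SNORD78	LSU-G4593	unknown
SNORD83b	5.8S-U14	unknown
SNORD89	SSU-U354	unknown
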