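pair_id	analyte_1	channel_1	analyte_2	channel_2	reason
hypoxanthine_allopurinol	Hypoxanthine	quantifier	Allopurinol	quantifier	shared parent m/z 137.1 in ESI+
uracilIS_dihydrouracil	Uracil-IS	quantifier	Dihydrouracil	quantifier	parent m/z 115.1 vs 115.0 in ESI+
deoxyguanosine_inosine	Deoxyguanosine	quantifier	Inosine	quantifier	parent m/z 266.1 vs 267.1 (1 Da) in ESI-
guanosineIS_orotidine	Guanosine-IS	quantifier	Orotidine	quantifier	shared parent m/z 287.1 in ESI-
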