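analyte	class	is_internal_standard	internal_standard	esi_mode	role	parent_mz	daughter_mz	cone_v	collision_v	retention_time_min
Uracil	pyrimidine	0	Uracil-IS	positive	quantifier	113.0	70.0	50	14	2.00
Uracil	pyrimidine	0	Uracil-IS	positive	qualifier	113.0	96.1	50	14	2.00
Dihydrouracil	pyrimidine	0	Dihydrouracil-IS	positive	quantifier	115.0	55.0	40	15	2.35
Dihydrouracil	pyrimidine	0	Dihydrouracil-IS	positive	qualifier	115.0	73.0	40	10	2.35
Uracil-IS	pyrimidine	1		positive	quantifier	115.1	71.0	30	14	2.00
Uracil-IS	pyrimidine	1		positive	qualifier	115.1	97.1	30	14	2.00
Dihydrouracil-IS	pyrimidine	1		positive	quantifier	121.0	58.0	40	16	2.35
Dihydrouracil-IS	pyrimidine	1		positive	qualifier	121.0	77.0	40	12	2.35
Thymine	pyrimidine	0	Thymine-IS	positive	quantifier	127.0	110.0	50	16	2.59
Thymine	pyrimidine	0	Thymine-IS	positive	qualifier	127.0	84.1	50	14	2.59
Dihydrothymine	pyrimidine	0	Dihydrothymine-IS	positive	quantifier	129.0	112.0	34	10	2.84
Dihydrothymine	pyrimidine	0	Dihydrothymine-IS	positive	qualifier	129.0	69.0	34	14	2.84
Thymine-IS	pyrimidine	1		positive	quantifier	131.1	114.1	40	15	2.59
Thymine-IS	pyrimidine	1		positive	qualifier	131.1	88.1	40	16	2.59
Beta-Ureidopropionic acid	pyrimidine	0	Uracil-IS	positive	quantifier	133.0	90.1	20	8	3.08
Beta-Ureidopropionic acid	pyrimidine	0	Uracil-IS	positive	qualifier	133.0	72.2	20	12	3.08
Dihydrothymine-IS	pyrimidine	1		positive	quantifier	135.1	74.1	30	14	2.84
Dihydrothymine-IS	pyrimidine	1		positive	qualifier	135.1	90.1	30	13	2.84
Beta-Ureidoisobutyric acid	pyrimidine	0	Uracil-IS	positive	quantifier	147.0	86.0	24	14	4.16
Beta-Ureidoisobutyric acid	pyrimidine	0	Uracil-IS	positive	qualifier	147.0	129.0	24	8	4.16
5-Hydroxymethyluracil	pyrimidine	0	Orotic Acid-IS	negative	quantifier	141.0	123.1	42	12	5.61
5-Hydroxymethyluracil	pyrimidine	0	Orotic Acid-IS	negative	qualifier	141.0	42.0	42	14	5.61
Orotic acid	pyrimidine	0	Orotic Acid-IS	negative	quantifier	155.0	111.0	34	10	5.86
Orotic acid	pyrimidine	0	Orotic Acid-IS	negative	qualifier	155.0	42.0	34	20	5.86
Orotic Acid-IS	pyrimidine	1		negative	quantifier	157.1	113.1	30	10	5.86
Orotic Acid-IS	pyrimidine	1		negative	qualifier	157.1	43.1	30	20	5.86
Deoxyuridine	pyrimidine	0	Guanosine-IS	negative	quantifier	227.0	184.1	44	12	6.10
Deoxyuridine	pyrimidine	0	Guanosine-IS	negative	qualifier	227.0	94.1	44	22	6.10
Thymidine	pyrimidine	0	Thymidine-IS	negative	quantifier	241.1	42.0	44	12	6.34
Thymidine	pyrimidine	0	Thymidine-IS	negative	qualifier	241.1	151.1	44	10	6.34
Pseudouridine	pyrimidine	0	Orotic Acid-IS	negative	quantifier	243.0	153.1	36	12	6.59
Pseudouridine	pyrimidine	0	Orotic Acid-IS	negative	qualifier	243.0	183.1	36	14	6.59
Thymidine-IS	pyrimidine	1		negative	quantifier	253.1	160.1	30	10	6.34
Thymidine-IS	pyrimidine	1		negative	qualifier	253.1	44.1	30	12	6.34
Orotidine	pyrimidine	0	Orotic Acid-IS	negative	quantifier	287.1	111.1	20	15	8.01
Orotidine	pyrimidine	0	Orotic Acid-IS	negative	qualifier	287.1	42.1	20	22	8.01
Adenine	purine	0	Xanthine-IS	positive	quantifier	136.0	92.0	66	24	3.32
Adenine	purine	0	Xanthine-IS	positive	qualifier	136.0	119.1	66	20	3.32
Hypoxanthine	purine	0	Hypoxanthine-IS	positive	quantifier	137.1	110.1	42	18	3.56
Hypoxanthine	purine	0	Hypoxanthine-IS	positive	qualifier	137.1	81.9	42	18	3.56
Allopurinol	purine	0	Hypoxanthine-IS	positive	quantifier	137.1	54.1	56	22	3.91
Allopurinol	purine	0	Hypoxanthine-IS	positive	qualifier	137.1	110.0	56	18	3.91
Hypoxanthine-IS	purine	1		positive	quantifier	142.0	114.1	40	20	3.56
Hypoxanthine-IS	purine	1		positive	qualifier	142.0	124.1	40	20	3.56
Xanthine	purine	0	Xanthine-IS	positive	quantifier	153.1	110.1	26	18	4.40
Xanthine	purine	0	Xanthine-IS	positive	qualifier	153.1	136.0	26	12	4.40
Xanthine-IS	purine	1		positive	quantifier	155.1	137.1	20	14	4.40
2,8-Dihydroxyadenine	purine	0	Xanthine-IS	positive	quantifier	168.1	125.0	66	18	4.64
2,8-Dihydroxyadenine	purine	0	Xanthine-IS	positive	qualifier	168.1	150.8	66	18	4.64
Deoxyadenosine	purine	0	Guanosine-IS	positive	quantifier	252.1	119.0	18	38	4.89
Deoxyadenosine	purine	0	Guanosine-IS	positive	qualifier	252.1	136.1	18	16	4.89
AICAr	purine	0	Guanosine-IS	positive	quantifier	259.2	110.1	26	22	5.13
AICAr	purine	0	Guanosine-IS	positive	qualifier	259.2	127.1	26	10	5.13
Adenosine	purine	0	Guanosine-IS	positive	quantifier	268.2	119.0	30	44	5.37
Adenosine	purine	0	Guanosine-IS	positive	qualifier	268.2	136.1	30	18	5.37
Guanosine-IS	purine	1		positive	quantifier	289.1	139.1	20	40	7.66
Guanosine-IS	purine	1		positive	qualifier	289.1	157.1	20	14	7.66
Deoxyinosine	purine	0	Guanosine-IS	negative	quantifier	251.1	135.1	56	22	6.83
Deoxyinosine	purine	0	Guanosine-IS	negative	qualifier	251.1	161.1	56	24	6.83
Deoxyguanosine	purine	0	Deoxyguanosine-IS	negative	quantifier	266.1	150.0	54	20	7.07
Deoxyguanosine	purine	0	Deoxyguanosine-IS	negative	qualifier	266.1	133.1	54	28	7.07
Inosine	purine	0	Inosine-IS	negative	quantifier	267.1	135.1	58	20	7.42
Inosine	purine	0	Inosine-IS	negative	qualifier	267.1	92.0	58	34	7.42
Inosine-IS	purine	1		negative	quantifier	271.1	139.1	20	20	7.42
Deoxyguanosine-IS	purine	1		negative	quantifier	281.1	160.1	20	20	7.07
Deoxyguanosine-IS	purine	1		negative	qualifier	281.1	142.1	20	30	7.07
Guanosine	purine	0	Guanosine-IS	negative	quantifier	282.1	150.0	48	18	7.66
Guanosine	purine	0	Guanosine-IS	negative	qualifier	282.1	133.1	48	30	7.66
Guanosine-IS	purine	1		negative	quantifier	287.1	155.1	20	18	7.66
Guanosine-IS	purine	1		negative	qualifier	287.1	137.1	20	30	7.66
SAICAr	purine	0	Guanosine-IS	negative	quantifier	373.1	355.1	20	18	8.26
SAICAr	purine	0	Guanosine-IS	negative	qualifier	373.1	294.1	20	20	8.26
Succinyladenosine	purine	0	Guanosine-IS	negative	quantifier	382.1	206.2	40	20	8.50
Succinyladenosine	purine	0	Guanosine-IS	negative	qualifier	382.1	134.1	40	30	8.50
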