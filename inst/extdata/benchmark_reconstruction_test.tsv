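empiar_id	method	particles_all	resolution_all	particles_select2d	resolution_select2d
10028	crYOLO	32687	4.13	31699	4.11
10081	crYOLO	44440	5.65	36821	4.97
10345	crYOLO	15821	3.98	11369	3.83
11056	crYOLO	60648	8.98	43599	8.32
10532	crYOLO	46162	4.23	29434	4.08
10093	crYOLO	43305	7.27	33183	6.87
10017	crYOLO	54263	4.99	47704	4.84
10028	Topaz	52588	3.98	35514	3.93
10081	Topaz	58217	6.13	37808	5.08
10345	Topaz	29208	3.73	21343	3.64
11056	Topaz	98680	8.11	66651	8.03
10532	Topaz	73196	4.54	38372	4.23
10093	Topaz	110577	6.35	61698	6.12
10017	Topaz	52875	5.13	45511	5.08
10028	CryoSegNet	47764	2.72	45218	2.72
10081	CryoSegNet	60158	4.58	44819	4.16
10345	CryoSegNet	25919	3.48	15209	2.84
11056	CryoSegNet	71342	7.83	53073	7.13
10532	CryoSegNet	67219	4.09	30155	3.89
10093	CryoSegNet	43886	7.27	27745	6.99
10017	CryoSegNet	11961	6.90	10026	6.86
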