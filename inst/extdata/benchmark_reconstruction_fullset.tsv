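empiar_id	method	particles_all	resolution_all	particles_select2d	resolution_select2d	original_resolution
10028	crYOLO	65376	3.97	63562	3.94	3.20
10345	crYOLO	50506	3.56	40047	3.54	3.51
10081	crYOLO	148488	4.26	123963	4.15	3.50
10532	crYOLO	232220	3.25	161497	3.22	2.90
10093	crYOLO	264447	4.54	192337	4.41	3.55
10028	Topaz	104652	2.72	96352	2.72	3.20
10345	Topaz	102977	3.50	87472	3.45	3.51
10081	Topaz	171396	4.34	130941	4.06	3.50
10532	Topaz	362115	3.52	206460	3.22	2.90
10093	Topaz	801208	4.55	437235	4.40	3.55
10028	CryoSegNet	93881	2.72	92532	2.72	3.20
10345	CryoSegNet	120357	2.74	73377	2.67	3.51
10081	CryoSegNet	202988	3.95	153333	3.45	3.50
10532	CryoSegNet	181259	3.42	90477	3.20	2.90
10093	CryoSegNet	267983	4.70	169330	4.54	3.55
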