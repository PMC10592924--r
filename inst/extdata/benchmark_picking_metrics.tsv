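empiar_id	protein_type	n_images	n_particles	method	precision	recall	f1	dice
10028	Ribosome (80S)	300	26391	crYOLO	0.807	0.941	0.869	0.863
10081	Transport	300	39352	crYOLO	0.822	0.884	0.852	0.822
10345	Signaling	295	15894	crYOLO	0.648	0.665	0.656	0.452
11056	Transport	305	125908	crYOLO	0.726	0.780	0.752	0.718
10532	Viral	300	87933	crYOLO	0.756	0.774	0.765	0.724
10093	Membrane	295	56394	crYOLO	0.623	0.744	0.678	0.641
10017	beta-galactosidase	84	49391	crYOLO	0.824	0.588	0.686	0.663
10028	Ribosome (80S)	300	26391	Topaz	0.696	0.937	0.799	0.786
10081	Transport	300	39352	Topaz	0.732	0.872	0.796	0.758
10345	Signaling	295	15894	Topaz	0.544	0.805	0.650	0.507
11056	Transport	305	125908	Topaz	0.764	0.909	0.830	0.778
10532	Viral	300	87933	Topaz	0.732	0.939	0.823	0.788
10093	Membrane	295	56394	Topaz	0.610	0.216	0.319	0.279
10017	beta-galactosidase	84	49391	Topaz	0.847	0.936	0.889	0.886
10028	Ribosome (80S)	300	26391	CryoSegNet	0.833	0.944	0.885	0.859
10081	Transport	300	39352	CryoSegNet	0.835	0.922	0.876	0.876
10345	Signaling	295	15894	CryoSegNet	0.746	0.920	0.824	0.743
11056	Transport	305	125908	CryoSegNet	0.757	0.687	0.720	0.663
10532	Viral	300	87933	CryoSegNet	0.796	0.628	0.702	0.649
10093	Membrane	295	56394	CryoSegNet	0.716	0.515	0.600	0.537
10017	beta-galactosidase	84	49391	CryoSegNet	0.859	0.616	0.718	0.703
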