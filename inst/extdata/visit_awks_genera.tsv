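body_region	body_habitat	awks	p_value	n_donors
Oral	Palatine Tonsils	0.160	<0.001	95
Oral	Subgingival plaque	0.147	<0.001	98
Oral	Supragingival plaque	0.133	<0.001	95
Oral	Throat	0.140	0.001	93
Skin	L Antecubital fossa	0.334	0.002	14
Oral	Keratinized gingiva	0.138	0.005	88
Stool	Stool	0.127	0.005	104
Oral	Saliva	0.114	0.016	83
Skin	R Antecubital fossa	0.291	0.023	13
Skin	L Retroauricular crease	0.154	0.024	66
Skin	Anterior nares	0.128	0.033	62
Oral	Tongue dorsum	0.092	0.120	99
Skin	R Retroauricular crease	0.109	0.152	75
Oral	Hard palate	0.095	0.186	86
Vaginal	Vaginal introitus	0.129	0.247	38
Oral	Buccal mucosa	0.078	0.405	99
Vaginal	Mid vagina	0.099	0.471	40
Vaginal	Posterior fornix	0.077	0.603	40
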