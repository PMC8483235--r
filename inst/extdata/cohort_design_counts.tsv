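cohort	group	metric	count
discovery	all	samples_total	1366
discovery	all	patients_total	423
discovery	visit_type	stable	920
discovery	visit_type	exacerbation	446
discovery	site	London	300
discovery	site	Leicester	303
discovery	site	Manchester	180
discovery	site	Southampton	583
discovery	state_samples	NH	153
discovery	state_samples	NB	313
discovery	state_samples	E	189
discovery	state_patients	NH	34
discovery	state_patients	NB	95
discovery	state_patients	E	43
validation	all	samples_total	340
validation	all	patients_total	87
validation	visit_type	stable	203
validation	visit_type	exacerbation	137
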