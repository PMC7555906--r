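sample_id	enhancement	truth	markers	trace	cohort_role	expected_level_I	expected_level_II	expected_level_III	expected_level_IV	comment
1S	none	bovine_blood	hbb_shared;hba_shared	FALSE	human_fp	yes	human	n/a	none-detected	recorded as the 1/40 human-blood false positive; outside the animal FN denominator
2S	none	human_blood	default	FALSE	normal	yes	human	n/a	none-detected	
3S	none	human_blood	default	FALSE	normal	yes	human	n/a	none-detected	
5S	AB-1	bovine_blood	hbb_shared;hba_shared	FALSE	animal	yes	human	n/a	none-detected	printed claim animal/bovine; under the HB-only model the HB pair reads human - only level-I detection enters the FN statistic
6S	none	human_blood	default	FALSE	normal	yes	human	n/a	none-detected	
7S	none	porcine_blood	none	FALSE	animal	no	n/a	n/a	none-detected	printed blood-yes/inconclusive; encoded markerless per the cohort aggregate (7/9 FN)
12S	none	sweat	none	FALSE	normal	no	n/a	n/a	none-detected	
13S	LCV	porcine_blood	none	FALSE	animal	no	n/a	n/a	none-detected	
14S	AB-1	human_blood	none	FALSE	normal	no	n/a	n/a	none-detected	human false negative; suspected mislabelling
16S	none	human_blood	default	FALSE	normal	yes	human	n/a	none-detected	
17S	none	human_blood	default	FALSE	normal	yes	human	n/a	none-detected	
18S	none	porcine_blood	hbb_shared	FALSE	animal	inconclusive	n/a	n/a	none-detected	wild boar; carries the shared beta-HB peptide only: level-I inconclusive, not a false negative
26S	LCV	saliva	none	FALSE	normal	no	n/a	n/a	none-detected	
27S	none	semen	default	FALSE	normal	no	n/a	n/a	none-detected	semen markers ignored by the initial strategy
28S	none	bovine_blood	none	FALSE	animal	no	n/a	n/a	none-detected	
29S	AY-7	chicken_blood	none	FALSE	animal	no	n/a	n/a	none-detected	
30S	AB-1	non_biofluid	none	FALSE	normal	no	n/a	n/a	none-detected	egg yolk
31S	LCV	human_blood	default	FALSE	normal	yes	human	n/a	none-detected	
34S	LCV	human_blood	default	FALSE	normal	yes	human	n/a	none-detected	EDTA anticoagulant
35S	none	chicken_blood	none	FALSE	animal	no	n/a	n/a	none-detected	
36S	none	non_biofluid	none	FALSE	normal	no	n/a	n/a	none-detected	ketchup
37S	none	human_blood	default	FALSE	normal	yes	human	n/a	none-detected	
40S	none	sweat	none	FALSE	normal	no	n/a	n/a	none-detected	
41S	AB-1	non_biofluid	none	FALSE	normal	no	n/a	n/a	none-detected	ketchup
49S	AB-1	saliva	none	FALSE	normal	no	n/a	n/a	none-detected	
53S	none	human_blood	default	FALSE	normal	yes	human	n/a	none-detected	EDTA anticoagulant
56S	none	porcine_blood	none	FALSE	animal	no	n/a	n/a	none-detected	
57S	none	non_biofluid	none	FALSE	normal	no	n/a	n/a	none-detected	paint
59S	none	human_blood	default	FALSE	normal	yes	human	n/a	none-detected	
60S	AY-7	saliva	none	FALSE	normal	no	n/a	n/a	none-detected	
61S	none	human_blood	default	FALSE	normal	yes	human	n/a	none-detected	
63S	LCV	chicken_blood	none	FALSE	animal	no	n/a	n/a	none-detected	faint enhancement
78S	none	non_biofluid	none	FALSE	normal	no	n/a	n/a	none-detected	body lotion
79S	none	blank	none	FALSE	normal	no	n/a	n/a	none-detected	
122F	AY-7	human_blood	default	FALSE	normal	yes	human	n/a	none-detected	
141F	AB-1	non_biofluid	none	FALSE	normal	no	n/a	n/a	none-detected	ketchup
160F	AY-7	saliva	none	FALSE	normal	no	n/a	n/a	none-detected	
162F	AB-1	human_blood	default	FALSE	normal	yes	human	n/a	none-detected	
165F	AY-7	non_biofluid	none	FALSE	normal	no	n/a	n/a	none-detected	egg white
175F	LCV	non_biofluid	none	FALSE	normal	no	n/a	n/a	none-detected	egg white
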