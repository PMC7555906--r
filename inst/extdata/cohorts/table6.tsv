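sample_id	enhancement	truth	markers	trace	cohort_role	expected_level_I	expected_level_II	expected_level_III	expected_level_IV	comment
15S	none	human_blood	default	FALSE	normal	yes	human	n/a	none-detected	
22S	AY-7	human_blood	default	FALSE	normal	yes	human	n/a	none-detected	
104F	none	chicken_blood	default	FALSE	animal	yes	animal	chicken	none-detected	
121F	none	saliva	none	FALSE	normal	no	n/a	n/a	none-detected	
127F	none	semen	default	FALSE	normal	no	n/a	n/a	semen	
128F	none	bovine_blood	default	FALSE	animal	yes	animal	bovine	none-detected	
129F	AY-7	chicken_blood	default	FALSE	animal	yes	animal	chicken	none-detected	
138F	AY-7	bovine_blood	myo_1593	FALSE	animal	yes	animal	inconclusive	none-detected	myoglobin nominal 1593 detected without mammalian GAPDH nominal 1764: animal blood, species inconclusive (the one partial claim)
146F	none	non_biofluid	none	FALSE	normal	no	n/a	n/a	none-detected	beet juice
147F	none	semen	default	FALSE	normal	no	n/a	n/a	semen	
155F	AY-7	porcine_blood	default	FALSE	animal	yes	animal	porcine	none-detected	
156F	none	porcine_blood	default	FALSE	animal	yes	animal	porcine	none-detected	
176F	AY-7	semen	default	FALSE	normal	no	n/a	n/a	semen	presumptive test positive, refuted
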