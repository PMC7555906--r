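sample_id	enhancement	truth	markers	trace	cohort_role	expected_level_I	expected_level_II	expected_level_III	expected_level_IV	comment
1S	none	bovine_blood	default	FALSE	animal	yes	animal	bovine	none-detected	revisited; correctly re-claimed bovine
2S	none	human_blood	default	FALSE	normal	yes	human	n/a	none-detected	
3S	none	human_blood	default	FALSE	normal	yes	human	n/a	none-detected	
5S	AB-1	bovine_blood	default	FALSE	animal	yes	animal	bovine	none-detected	
6S	none	human_blood	default	FALSE	normal	yes	human	n/a	none-detected	
7S	none	porcine_blood	default	FALSE	animal	yes	animal	porcine	none-detected	printed claim inconclusive at II-III; not reproduced (encoded with the default porcine marker set)
10S	none	chicken_blood	default	FALSE	animal	yes	animal	chicken	none-detected	reconstructed: chicken bloodstain discussed in the narrative but absent from the printed list; added to match the cohort totals (56 samples, 15 animal, 5 chicken)
12S	none	sweat	none	FALSE	normal	no	n/a	n/a	none-detected	
13S	LCV	porcine_blood	none	FALSE	animal	no	n/a	n/a	none-detected	original no longer available, could not be re-processed: the single post-refinement animal false negative
14S	AB-1	human_blood	none	FALSE	normal	no	n/a	n/a	none-detected	human false negative; suspected mislabelling
16S	none	human_blood	default	FALSE	normal	yes	human	n/a	none-detected	
17S	none	human_blood	default	FALSE	normal	yes	human	n/a	none-detected	
18S	none	porcine_blood	default	FALSE	animal	yes	animal	porcine	none-detected	wild boar, reported as porcine
26S	LCV	saliva	none	FALSE	normal	no	n/a	n/a	none-detected	
27S	none	semen	default	FALSE	normal	no	n/a	n/a	semen	
28S	none	bovine_blood	default	FALSE	animal	yes	animal	bovine	none-detected	revisited
29S	AY-7	chicken_blood	default	FALSE	animal	yes	animal	chicken	none-detected	revisited
30S	AB-1	non_biofluid	none	FALSE	normal	no	n/a	n/a	none-detected	egg yolk
31S	LCV	human_blood	default	FALSE	normal	yes	human	n/a	none-detected	
32S	LCV	semen	default	FALSE	normal	no	n/a	n/a	semen	revisited after the semenogelin marker was retrieved
34S	LCV	human_blood	default	FALSE	normal	yes	human	n/a	none-detected	EDTA anticoagulant
35S	none	chicken_blood	default	FALSE	animal	yes	animal	chicken	none-detected	revisited
36S	none	non_biofluid	none	FALSE	normal	no	n/a	n/a	none-detected	ketchup
37S	none	human_blood	default	FALSE	normal	yes	human	n/a	none-detected	
40F	none	sweat	none	FALSE	normal	no	n/a	n/a	none-detected	
41S	AB-1	non_biofluid	none	FALSE	normal	no	n/a	n/a	none-detected	ketchup
49S	AB-1	saliva	none	FALSE	normal	no	n/a	n/a	none-detected	
53S	none	human_blood	default	FALSE	normal	yes	human	n/a	none-detected	EDTA anticoagulant
56S	none	porcine_blood	default	FALSE	animal	yes	animal	porcine	none-detected	revisited
57S	none	non_biofluid	none	FALSE	normal	no	n/a	n/a	none-detected	paint
58S	AB-1	semen	default	FALSE	normal	no	n/a	n/a	semen	presumptive test positive, refuted
59S	none	human_blood	default	FALSE	normal	yes	human	n/a	none-detected	
60S	AY-7	saliva	none	FALSE	normal	no	n/a	n/a	none-detected	
61S	none	human_blood	default	FALSE	normal	yes	human	n/a	none-detected	
63S	LCV	chicken_blood	default	FALSE	animal	yes	animal	chicken	none-detected	revisited
78S	none	non_biofluid	none	FALSE	normal	no	n/a	n/a	none-detected	body lotion
79S	none	blank	none	FALSE	normal	no	n/a	n/a	none-detected	revisited
122F	AY-7	human_blood	default	FALSE	normal	yes	human	n/a	none-detected	
132F	LCV	semen	default	FALSE	normal	no	n/a	n/a	semen	
141F	AB-1	non_biofluid	none	FALSE	normal	no	n/a	n/a	none-detected	ketchup
158F	AB-1	semen	default	FALSE	normal	no	n/a	n/a	semen	presumptive test positive, refuted
160F	AY-7	saliva	none	FALSE	normal	no	n/a	n/a	none-detected	
162F	AB-1	human_blood	default	FALSE	normal	yes	human	n/a	none-detected	
165F	AY-7	non_biofluid	none	FALSE	normal	no	n/a	n/a	none-detected	egg white
175F	LCV	non_biofluid	none	FALSE	normal	no	n/a	n/a	none-detected	egg white
4F	none	chicken_blood	default	FALSE	animal	yes	animal	chicken	none-detected	new post-refinement sample
24S	none	non_biofluid	none	FALSE	normal	no	n/a	n/a	none-detected	egg; new post-refinement sample
25S	LCV	bovine_blood	default	FALSE	animal	yes	animal	bovine	none-detected	new post-refinement sample
41S-2	AB-1	non_biofluid	none	FALSE	normal	no	n/a	n/a	none-detected	ketchup; new post-refinement sample (reused number)
44S	none	porcine_blood	default	FALSE	animal	yes	animal	porcine	none-detected	wild boar, reported as porcine; new post-refinement sample
53S-2	none	human_blood	default	FALSE	normal	yes	human	n/a	none-detected	EDTA; new post-refinement sample (reused number)
72S	none	non_biofluid	none	FALSE	normal	no	n/a	n/a	none-detected	steak sauce; new post-refinement sample
76S	AY-7	semen	default	FALSE	normal	no	n/a	n/a	semen	new post-refinement sample
107F	none	porcine_blood	default	FALSE	animal	yes	animal	porcine	none-detected	new post-refinement sample
144F	none	blank	none	FALSE	normal	no	n/a	n/a	none-detected	new post-refinement sample
170F	none	human_blood	none	TRUE	normal	no	n/a	n/a	none-detected	human blood trace from the last mark of a depletion series; all markers below sensitivity
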