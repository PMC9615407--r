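token	category	action
rx_cardiovascular_disease_1	cardiovascular_disease	include
rx_cardiovascular_disease_2	cardiovascular_disease	include
rx_chronic_pain_1	chronic_pain	include
rx_chronic_pain_2	chronic_pain	include
rx_arthritis_1	arthritis	include
rx_arthritis_2	arthritis	include
rx_affective_disorders_1	affective_disorders	include
rx_affective_disorders_2	affective_disorders	include
rx_acid_related_disorders_1	acid_related_disorders	include
rx_acid_related_disorders_2	acid_related_disorders	include
rx_asthma_copd_1	asthma_copd	include
rx_asthma_copd_2	asthma_copd	include
rx_diabetes_mellitus_1	diabetes_mellitus	include
rx_diabetes_mellitus_2	diabetes_mellitus	include
rx_osteoporosis_1	osteoporosis	include
rx_osteoporosis_2	osteoporosis	include
rx_thyroid_disease_1	thyroid_disease	include
rx_thyroid_disease_2	thyroid_disease	include
rx_thromboembolic_disease_1	thromboembolic_disease	include
rx_thromboembolic_disease_2	thromboembolic_disease	include
rx_inflammatory_conditions_1	inflammatory_conditions	include
rx_inflammatory_conditions_2	inflammatory_conditions	include
rx_benign_prostatic_hyperplasia_1	benign_prostatic_hyperplasia	include
rx_benign_prostatic_hyperplasia_2	benign_prostatic_hyperplasia	include
rx_gout_1	gout	include
rx_gout_2	gout	include
rx_glaucoma_1	glaucoma	include
rx_glaucoma_2	glaucoma	include
rx_urinary_incontinence_1	urinary_incontinence	include
rx_urinary_incontinence_2	urinary_incontinence	include
rx_erectile_dysfunction_1	erectile_dysfunction	include
rx_erectile_dysfunction_2	erectile_dysfunction	include
rx_psychotic_disorders_1	psychotic_disorders	include
rx_psychotic_disorders_2	psychotic_disorders	include
rx_epilepsy_1	epilepsy	include
rx_epilepsy_2	epilepsy	include
rx_migraine_1	migraine	include
rx_migraine_2	migraine	include
rx_parkinsonism_1	parkinsonism	include
rx_parkinsonism_2	parkinsonism	include
rx_dementia_1	dementia	include
rx_dementia_2	dementia	include
rx_tricyclic		exclude
rx_broad_spectrum_analgesic		exclude
rx_multivitamin		exclude
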