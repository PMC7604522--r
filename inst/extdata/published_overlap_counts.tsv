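quantity	numerator	denominator
cis_elncrna_single_cohort	1150	4742
cis_elncrna_gt8_cohorts	237	4742
trans_elncrna_single_cohort	1730	3284
cis_elncrna_disease_annotated	462	4742
trans_elncrna_disease_annotated	679	3284
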