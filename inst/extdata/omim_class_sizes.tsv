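class	n_genes
Bone	38
Cancer	172
Cardiovascular	126
Connective tissue disorder	46
Dermatological	76
Developmental	55
Ear Nose Throat	39
Endocrine	84
Gastrointestinal	26
Hematological	68
Immunological	91
Metabolic	184
Multiple	187
Muscular	60
Neurological	232
Nutritional	18
Ophthamological	92
Psychiatric	31
Renal	45
Respiratory	47
Skeletal	58
Unclassified	14
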