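term	semantic_type	in_chv	familiarity
thrombocytosis	Disease or syndrome	1	0.21
crohn disease	Disease or syndrome	1	0.35
budesonide	Organic chemical	1	0.28
diabetes mellitus	Disease or syndrome	1	0.72
metformin	Organic chemical	1	0.55
complete blood count	Diagnostic procedure	1	0.48
platelet count	Diagnostic procedure	1	0.44
gastrointestinal bleeding	Pathologic function	1	0.52
hematemesis	Finding	1	0.18
epistaxis	Finding	1	0.22
tuberculosis	Disease or syndrome	1	0.81
oncologist	other	1	0.77
insulin	Amino acid, peptide, or protein	1	0.84
retinopathy	Disease or syndrome	1	0.31
renal dysfunction	Pathologic function	1	0.33
iron	Organic chemical	1	0.92
iron deficiency	Disease or syndrome	1	0.61
disease	other	1	0.97
lymphoma	Neoplastic process	1	0.58
non hodgkin lymphoma	Neoplastic process	1	0.30
stem cell transplant	Therapeutic or preventive procedure	1	0.41
autologous stem cell transplant	Therapeutic or preventive procedure	0	NA
chemotherapy	Therapeutic or preventive procedure	1	0.78
warfarin	Organic chemical	1	0.49
thyroid ultrasound	Diagnostic procedure	1	0.43
prostate	other	1	0.74
blood	other	1	0.99
pain	Finding	1	0.98
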