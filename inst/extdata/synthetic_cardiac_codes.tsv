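code	vocabulary	subtype
7451	ICD9	conotruncal
7453	ICD9	single_ventricle
7454	ICD9	ventricular_septal
7455	ICD9	atrial_septal
7456	ICD9	atrioventricular_septal
7460	ICD9	right_sided
7467	ICD9	left_sided
7470	ICD9	pda
7478	ICD9	pphn
7474	ICD9	great_veins
7468	ICD9	other
Q200	ICD10	conotruncal
Q204	ICD10	single_ventricle
Q210	ICD10	ventricular_septal
Q211	ICD10	atrial_septal
Q212	ICD10	atrioventricular_septal
Q220	ICD10	right_sided
Q234	ICD10	left_sided
Q250	ICD10	pda
Q253	ICD10	pphn
Q262	ICD10	great_veins
Q248	ICD10	other
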