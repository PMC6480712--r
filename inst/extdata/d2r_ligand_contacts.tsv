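ligand	residue	category
risperidone	Trp100^ECL1	unique
risperidone	Ser197^5.48	unique
risperidone	Phe382^6.44	unique
risperidone	Tyr416^7.43	unique
risperidone	Asp114^3.32	I
risperidone	Cys118^3.36	III
risperidone	Ile122^3.40	III
risperidone	Trp386^6.48	II
risperidone	Phe389^6.51	II
clozapine	Phe189^5.38	unique
clozapine	Phe198^5.47	unique
clozapine	Phe390^6.52	unique
clozapine	His393^6.55	unique
clozapine	Asp114^3.32	I
clozapine	Val115^3.33	IV
clozapine	Ile184^ECL2	IV
clozapine	Ser193^5.42	IV
clozapine	Trp386^6.48	II
clozapine	Phe389^6.51	II
spiperone	Val91^2.61	unique
spiperone	Phe110^3.28	unique
spiperone	Asp114^3.32	I
spiperone	Val115^3.33	IV
spiperone	Cys118^3.36	III
spiperone	Ile122^3.40	III
spiperone	Ile184^ECL2	IV
spiperone	Ser193^5.42	IV
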