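sample_group	description	n_reads
MR-antibiotic treated	Antibiotic treatment- Moyo-R strain	3293734
MR-antibiotic untreated	No antibiotic treatment- Moyo-R strain	3565178
MS-antibiotic treated	Antibiotic treatment- Moyo-S strain	3816752
MS-antibiotic untreated	No antibiotic treatment- Moyo-S strain	3618226
MR-DENV	DENV challenge- Moyo-R strain	8546216
MR-Control	Control: No DENV challenge- Moyo-R strain	10756770
MS-DENV	DENV challenge- Moyo-S strain	8281386
MS-Control	Control: No DENV challenge- Moyo-S strain	8783758
MR-immature	Immature larvae (stages 2,3 and 4)- Moyo-R strain	4219050
MR-adults	Moyo-R adults (mixed sex)	802882
MS-immature	Immature larvae (stages 2,3 and 4)- Moyo-S strain	4251764
MS-Adults	Moyo-S adults (mixed sex)	931800
Males	Males from 5 strains	9574404
Females	Females from 5 strains	8867864
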