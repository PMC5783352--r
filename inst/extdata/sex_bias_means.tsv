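gene_id	trna_type	trf_class	mean_female	mean_male	bias
AAEL016015	Gly-GCC	3-Pre	17334.6	10792.4	Female biased
AAEL016012	Asp-GTC	3-Pre	481.4	309.4	Female biased
AAEL016867	Ala-AGC	5-Pre	427.4	148.8	Female biased
AAEL016866	Lys-TTT	5-Pre	195.2	61	Female biased
AAEL016846	Ala-AGC	3-Pre	2454	4642.6	Male biased
AAEL016845	Ala-AGC	3-Pre	2387.8	4531.8	Male biased
AAEL016779	Thr-TGT	A-loop	526.4	634.8	Male biased
AAEL016742	Ala-AGC	T-loop	159.2	432.8	Male biased
AAEL016064	Pro-CGG	5tRF	246	329.8	Male biased
AAEL016743	Trp-CCA	T-loop	156	419.6	Male biased
AAEL016534	Asp-GTC	3-Pre	118.8	237.4	Male biased
AAEL016533	Gly-GCC	3-Pre	114.8	225	Male biased
AAEL016390	Glu-CTC	5-Pre	114.6	214.2	Male biased
AAEL016947	Gln-CTG	T-loop	127	162	Male biased
AAEL016948	Ala-AGC	T-loop	120.2	159	Male biased
AAEL016542	Phe-GAA	3-Pre	45.8	126	Male biased
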