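subject	diagnosis	gene	depth	allele_fraction	cadd	exac_af	consequence
4999	ASD	CHD8	210	0.48	32.0	NA	stop_gained
5144	ASD	SCN2A	185	0.51	29.5	0.00001	missense_variant
5176	ASD	SHANK3	240	0.46	31.2	NA	missense_variant
5403	ASD	SYNGAP1	156	0.52	27.8	0.000005	missense_variant
4899	ASD	ADNP	199	0.49	33.6	NA	stop_gained
4917	ASD	ARID1B	175	0.50	28.9	0.00002	missense_variant
5027	ASD	DYRK1A	222	0.47	30.4	NA	splice_donor_variant
5115	ASD	GRIN2B	143	0.53	26.7	0.00008	missense_variant
5302	ASD	POGZ	188	0.45	29.1	NA	missense_variant
5565	ASD	KMT2A	265	0.50	25.9	0.00003	missense_variant
5678	ASD	TBR1	172	0.48	31.8	NA	stop_gained
5702	ASD	CHD8	205	0.52	30.6	NA	missense_variant
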