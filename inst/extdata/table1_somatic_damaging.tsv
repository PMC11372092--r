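subject	diagnosis	gene	hgvs	vaf	gnomad_af	consequence	cadd	validated
4999	ASD	DVL1	NM_001330311.2:c.196C>A(p.D66Y)	0.003	NA	missense_variant	25.1	TRUE
4999	ASD	ADCY5	NM_001199642.1:c.2101G>A(p.H701Y)	0.010	NA	missense_variant	28.3	TRUE
5144	ASD	ERBB3	NM_001982.3:c.1611T>G(p.N537K)	0.020	NA	missense_variant	24.6	TRUE
5176	ASD	PEAK1	NM_024776.3:c.890C>T(p.R297Q)	0.025	0.00000402	missense_variant	26.0	TRUE
5403	ASD	RGS6	NM_001204424.2:c.335G>A(p.R112H)	0.030	0.0000199	missense_variant	23.4	TRUE
5308	ASD	SLC25A22	NM_001191060.1:c.718C>T(p.A240T)	0.038	0.00000401	missense_variant	27.7	TRUE
5841	ASD	CENPJ	NM_018451.5:c.3001G>T(p.Q1001K)	0.017	NA	missense_variant	22.9	TRUE
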