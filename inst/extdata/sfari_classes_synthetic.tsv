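gene	class
CHD8	1
SCN2A	1
SHANK3	1
SYNGAP1	1
ADNP	1
ARID1B	1
DYRK1A	1
GRIN2B	2
POGZ	2
KMT2A	2
TBR1	3
SLC25A22	3
ERBB3	other
TTN	other
OBSCN	other
MUC16	other
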