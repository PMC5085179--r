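gene	missense	synonymous	nonsense
CASP3	3	2	1
CASP6	0	0	0
CASP8	4	1	2
CFLAR	1	1	0
CHUK	2	0	1
DECOY1	0	0	0
FADD	1	2	0
NFKB1	3	1	1
NFKBIA	2	1	0
RIPK1	2	3	1
TNFRSF1A	3	1	1
TRADD	0	1	0
TRAF2	0	0	1
XIAP	1	2	0
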