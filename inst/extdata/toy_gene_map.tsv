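parameter_id	gene	excluded
kp_rec	NA	TRUE
kd_rec	TNFRSF1A	FALSE
ka_bind	TNFRSF1A	FALSE
kd_c1	TRADD	FALSE
ka_c1c2	RIPK1	FALSE
ka_c1c2b	TRAF2	FALSE
kd_c2	FADD	FALSE
kp_nfkb	NA	TRUE
kd_nfkbi	NFKB1	FALSE
ka_nfkb	CHUK	FALSE
ki_nfkb	NFKBIA	FALSE
kp_iap	NA	TRUE
kd_iap	XIAP	FALSE
kp_c8	NA	TRUE
kd_c8i	CASP8	FALSE
ka_c8	CASP8	FALSE
ka_c8b	CASP8	FALSE
kd_c8	CASP8	FALSE
ki_c8	CFLAR	FALSE
kp_pro3	NA	TRUE
kd_pro3	CASP3	FALSE
ka_c3	CASP3	FALSE
ka_c3b	CASP3	FALSE
ka_auto	CASP3	FALSE
kd_c3	CASP3	FALSE
ki_c3	XIAP	FALSE
ka_c6	CASP6	FALSE
kd_c6	CASP6	FALSE
kp_dec	NA	TRUE
kd_dec	DECOY1	FALSE
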