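name	pattern	family	zone	maxMismatch
octapeptide_pax19	H[ST]V[ST][DN][IL]LG	Pax1/9	post_prd	0
octapeptide_pax258	Y[TS]IX2ILG	Pax2/5/8	post_prd	0
poxn_junction	KPKQVAT	PoxNeuro	prd_junction	0
poxn_post_prd	[VI]PGLSYP[KR][IL]V	PoxNeuro	post_prd	0
mdkl_linker	MDKL	Pax4/6	prd_hd_linker	0
paxbeta_m1	YDY[NS]LPDRGL	Paxβ	post_prd	0
paxbeta_m2	PLDLS	Paxβ	post_prd	0
paxbeta_m3	Y[ED][RK]N[LVM]L[LI]FGD[SNQ]E[IVL]EI[MI]SVGKX[KR]W[IV][VI]RNEX[DE]L	Paxβ	post_prd	2
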