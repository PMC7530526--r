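HALLMARK_MYOGENESIS_SYNTHETIC	Synthetic 200-gene myogenesis signature stand-in (curated human muscle gene symbols)	ACTA1	ACTC1	ACTN2	ACTN3	MYOG	MYF5	MYF6	MYOD1	MEF2A	MEF2C	MEF2D	DES	TTN	NEB	TNNT1	TNNT2	TNNT3	TNNI1	TNNI2	TNNC1	TNNC2	TPM1	TPM2	TPM3	MYL1	MYL2	MYL3	MYL4	MYLPF	MYH1	MYH2	MYH3	MYH4	MYH7	MYH8	MYBPC1	MYBPC2	MYBPH	CKM	CKMT2	MB	CAV3	SGCA	SGCB	SGCD	SGCG	DTNA	DAG1	SNTA1	SSPN	CAPN3	DYSF	LAMA2	ITGA7	ITGB1BP2	VCL	PAX7	PAX3	SIX1	SIX4	EYA1	EYA2	SRF	TEAD1	TEAD4	CASQ1	CASQ2	RYR1	ATP2A1	ATP2A2	PLN	SLN	CACNA1S	CACNB1	CACNG1	CHRNA1	CHRNB1	CHRND	CHRNE	CHRNG	MUSK	AGRN	RAPSN	UTRN	ANKRD1	ANKRD2	CSRP3	LDB3	PDLIM3	PDLIM5	MYOZ1	MYOZ2	MYOZ3	TCAP	MYOT	FLNC	BAG3	CRYAB	HSPB2	HSPB3	HSPB7	HSPB8	SMYD1	TRIM63	FBXO32	GAA	PYGM	PGAM2	ENO3	PFKM	ALDOA	GYS1	PHKA1	AMPD1	CA3	SPEG	OBSCN	NRAP	LMOD1	LMOD2	LMOD3	TMOD1	TMOD4	KLHL31	KLHL40	KLHL41	KBTBD13	CFL2	SYNPO2	SYNPO2L	PDLIM7	FHL1	FHL2	FHL3	XIRP1	XIRP2	MYPN	MYOM1	MYOM2	MYOM3	SMPX	STAC3	JPH1	JPH2	TRDN	SRL	CACNA2D1	SCN4A	SCN4B	CLCN1	ATP1A2	ANO5	MTM1	BIN1	DNM2	IGF1	IGF2	IGFBP5	MSTN	FST	HGF	MET	CDH15	CDON	BOC	NCAM1	MYMK	VGLL2	APOBEC2	DMPK	CNN3	SORBS1	SORBS2	SVIL	KY	MYLK2	MYLK4	MYO18B	TNNI3	ACHE	COL19A1	COX6A2	COX7A1	COX8A	CYCS	NDUFA11	SLC25A4	CPT1B	PPARGC1A	ESRRA	TEAD2	NOTCH1	HEY1	HES1	NOG	BMP4	WNT4	SHH	PTCH1	GLI2
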