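patient_id	germline_variants	somatic_right	somatic_left	shared_variants	shared_status	adjacent_kidney	blood_gom
SJWLM066770	REST:p.H379P	DHX36,EIF1AX,HCG22,RPS10P7	ALPK2,BCORL1,GUSBP4,H3F3A,IZKF4,PLCH2,PPFIA4,RBBP4,STAT4,REST,IL2RB,GRLF1,LRRC16B		LOH	NA	No
SJWLM066771		VCX3A	LOC26102,PPCDC,R3HDM1		LOI	NA	Yes
SJWLM066773	TRIM28:p.Q318*,BRCA1:p.Q687P	CDK13,TAS2R60	ITM2C,LOC100133161,LOC339822		ROI	NA	No
SJWLM066776	WT1:p.Q253*	AIM1L,CAMK2B,CTNNB1:p.T41A,DHX30,EBF4,NLRC5,OR4C11,PPL	CTNNB1:p.S45del,DBH,DDX60,NANOS1,NELL1,TUBB1,ZFHX4,ATE1,RERE		LOH	ROI R + L	No
SJWLM066777	TRIM28:p.R795C	NCRNA00245,TCHH	C14orf73,REG3A,SLC12A1		ROI	NA	No
SJWLM066778		GPR97,IL31RA,RAD17	CYC1,EMX2OS,KIAA0664,KIF6,MAML3,NES,NR0B1,PKHD1L1,SRRM5,TBX4,TRMT61B,ZNF833P		LOI	ROI L	No
SJWLM066779	BLM:p.K323R	ATP6AP2,C22orf34,DACH1,DROSHA,MAP7D3,PITPNM2,SIX1	ABCC12,DGCR8,LOC401177,MARCH7,SLC17A7,SIDT2		LOI	LOI L	No
SJWLM066780	WT1:p.E401fs	ARHGAP9,C1orf106,CHST3,CTNNB1:p.S45F,OSBPL8,PSME3,RYR1	C5orf46,CTNNB1:p.S45F,LOC283392,OR52K2,SHROOM2	CTNNB1:p.S45F	LOH	ROI L	No
SJWLM066784		NRP1,ZNF469	AZU1,C10orf71,DGCR8,DSCAML1,RNASEK		LOI	ROI R + L	Yes
SJWLM066789	DICER1:M1402_E23_splice	CTNNB1,FAM120C,GPR27,LOC730755,PP1R13L,RPAP1,SRRSF4,TYRO3,ZNF775	ACTR10,BICD2,C10orf108,C1orf86,C21orf122,DSC2,IDH3G,KCND3,KIAA0125,NBEAL2		LOH	LOH L	No
SJWLM066792	NYNRIN:p.R1592*,ASXL1:p.V1297I	DNHD1,MAP3K4,QSOX2,SPERT,TROAP			LOI	LOI L	No
SJWLM069391		CRAT,ROS1:p.Q1889fs	NPRL3,ROS1:p.Q1889fs	ROS1:p.Q1889fs	LOI	NA	No
SJWLM069394		SMC1A	EIF1AX,GSPT2,MAP3K4,TRIO,UNC80,VILL		NOT_SHARED	NA	No
SJWLM069396	WT1:p.R441*		APOB,NBEAL2,PACS2,KCNQ1		LOH	NA	No
SJWLM069399		SPTBN5	CHST6,CLIP1,DGCR8,MAGI3,RERE,SMC1B		LOI	NA	Yes
SJWLM044978		MCPH1,STK10	ATP6V1B2,C9orf131,DOCK9,LCN10,MDN1,PRRC2B,SLC6A20,TP53,ZNF805		LOI	NA	No
SJWLM051020		HIST1H3I,ZNF664	HEATR3		LOI	NA	Yes
SJWLM051024	WT1:p.T305fs	NLGN3,UBE4A,ZFHX2,CTNNB1	FAM199X,DSPP,PPP1R11		LOH	NA	No
SJWLM051026		ACTB,AMAC1,AP2B1,LDHAL6B,LZTR1,NKX2-1,PRRC2B,SEC14L3,TP53,TTC17	CHD4,EVC,RBMX,CASQ2		LOI	NA	No
SJWLM051028	WT1:p.Y337*	GLDN,GPR149,CTNNB1:p.S45P	CCDC61,CTNNB1:p.S45del,FAM159B,SNTG1,ZNF324,AEBP1		LOH	NA	Yes
SJWLM018908		CRIPAK,TMEM151B			LOI	NA	Yes
SJWLM043953	CDC73:p.M1T	ANKRD34B,DNAH5,FRG1			ROI	NA	No
SJWLM051025		RYR1,IRS4			LOI	NA	Yes
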