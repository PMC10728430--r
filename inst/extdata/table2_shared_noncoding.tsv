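patient_id	tumor1_noncoding	tumor2_noncoding	shared_noncoding	icr_status	germline_genes	cnv_similarity
SJWLM066770	136	119	0	LOH	REST	NA
SJWLM066771	54	74	6	LOI		NA
SJWLM066773	38	41	0	ROI	TRIM28,BRCA1	NA
SJWLM066776	122	174	5	LOH	WT1	NA
SJWLM066777	69	59	0	ROI	TRIM28	NA
SJWLM066778	379	68	1	LOI		NA
SJWLM066779	83	230	0	LOI	BLM	NA
SJWLM066780	97	104	0	LOH	WT1	NA
SJWLM066784	73	83	1	LOI		NA
SJWLM066789	125	58	2	LOH	DICER1	NA
SJWLM066792	79	16	1	LOI	ASXL1,NYNRIN	NA
SJWLM069391	102	121	63	LOI		0.95
SJWLM069394	43	104	1	LOI/ROI		NA
SJWLM069396	38	90	2	LOH	WT1	NA
SJWLM069399	136	55	1	LOI		NA
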