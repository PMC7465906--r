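protein_id	name	start	end	disorder_flag	functional_unit
APC	APC_1284-1537	1284	1537	TRUE	domain
ASXL1	ASXL1_1102-1107	1102	1107	TRUE	motif
BCL2	BCL2_2-80	2	80	TRUE	domain
CALR	CALR_358-384	358	384	TRUE	domain
CARD11	CARD11_111-134	111	134	TRUE	linker
CARD11	CARD11_207-266	207	266	TRUE	linker
CARD11	CARD11_337-436	337	436	TRUE	linker
CBL	CBL_365-374	365	374	TRUE	linker
CCND3	CCND3_278-290	278	290	TRUE	motif
CD79B	CD79B_191-199	191	199	TRUE	motif
CEBPA	CEBPA_293-327	293	327	TRUE	motif
CSF1R	CSF1R_969-969	969	969	TRUE	motif
CTNNB1	CTNNB1_32-45	32	45	TRUE	motif
EIF1AX	EIF1AX_4-15	4	15	TRUE	motif
EPAS1	EPAS1_529-539	529	539	TRUE	motif
ESR1	ESR1_303-303	303	303	TRUE	motif
FOXA1	FOXA1_248-268	248	268	TRUE	linker
FOXL2	FOXL2_134-134	134	134	TRUE	motif
FOXO1	FOXO1_19-26	19	26	TRUE	motif
HIST1H3B	HIST1H3B_28-28	28	28	TRUE	motif
ID3	ID3_48-70	48	70	TRUE	domain
MED12	MED12_44-44	44	44	TRUE	motif
MLH1	MLH1_379-385	379	385	TRUE	linker
MYC	MYC_57-60	57	60	TRUE	motif
MYCN	MYCN_44-44	44	44	TRUE	motif
MYOD1	MYOD1_122-122	122	122	TRUE	motif
NFE2L2	NFE2L2_20-38	20	38	TRUE	motif
NFE2L2	NFE2L2_75-82	75	82	TRUE	motif
PAX5	PAX5_75-80	75	80	TRUE	motif
RPS15	RPS15_129-145	129	145	TRUE	domain
SETBP1	SETBP1_858-880	858	880	TRUE	motif
SMARCB1	SMARCB1_368-381	368	381	TRUE	domain
SRSF2	SRSF2_95-95	95	95	TRUE	motif
USP8	USP8_713-736	713	736	TRUE	linker
VHL	VHL_54-136	54	136	TRUE	domain
VHL	VHL_144-193	144	193	TRUE	domain
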