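class_code	base_formula	n_chains	c_min	c_max	db_min	db_max	adducts_pos	adducts_neg	internal_standard	anchor_c	anchor_db	anchor_formula
CE	C27H44O2	1	12	40	0	8	[M+NH4]+,[M+Na]+		CE(16:0)-d7	16	0	C43H76O2
LPC	C8H18NO7P	1	12	32	0	8	[M+H]+,[M+Na]+	[M+HCOO]-	LPC(14:0)	14	0	C22H46NO7P
LPE	C5H12NO7P	1	12	32	0	8	[M+H]+	[M-H]-	LPE(14:0)	14	0	C19H40NO7P
LPE[O]	C5H14NO6P	1	12	32	0	8	[M+H]+	[M-H]-	LPE(14:0)	16	0	C21H46NO6P
LPE[P]	C5H12NO6P	1	12	32	0	8	[M+H]+	[M-H]-	LPE(14:0)	18	0	C23H48NO6P
LPA	C3H7O7P	1	12	28	0	6		[M-H]-	LPA(14:0)	14	0	C17H35O7P
LPG	C6H13O9P	1	12	28	0	6		[M-H]-	LPG(14:0)	14	0	C20H41O9P
LPI	C9H17O12P	1	12	28	0	6		[M-H]-	PI(16:0)	16	0	C25H49O12P
FA	O2	1	12	36	0	8		[M-H]-	LPC(14:0)	16	0	C16H32O2
PC	C8H16NO8P	2	24	60	0	12	[M+H]+,[M+Na]+	[M+HCOO]-	PC(28:0)	28	0	C36H72NO8P
PC[O]	C8H18NO7P	2	24	60	0	12	[M+H]+,[M+Na]+	[M+HCOO]-	PC(28:0)	32	0	C40H82NO7P
PE	C5H10NO8P	2	24	60	0	12	[M+H]+	[M-H]-	PE(28:0)	28	0	C33H66NO8P
PE[O]	C5H12NO7P	2	24	60	0	12	[M+H]+	[M-H]-	PE(28:0)	34	1	C39H78NO7P
PE[P]	C5H10NO7P	2	24	60	0	12	[M+H]+	[M-H]-	PE(28:0)	34	1	C39H76NO7P
PG	C6H11O10P	2	24	52	0	10		[M-H]-	PG(28:0)	28	0	C34H67O10P
PS	C6H10NO10P	2	24	52	0	10		[M-H]-	PS(28:0)	28	0	C34H66NO10P
PA	C3H5O8P	2	24	52	0	10		[M-H]-	PA(28:0)	28	0	C31H61O8P
PI	C9H15O13P	2	24	52	0	10		[M-H]-	PI(16:0)	16	0	C25H47O13P
DG	C3H4O5	2	24	60	0	12	[M+NH4]+,[M+Na]+		DG(28:0)	28	0	C31H60O5
SM[d]	C5H13N2O6P	2	28	48	0	6	[M+H]+,[M+Na]+	[M+HCOO]-	SM[d](30:1)	30	1	C35H71N2O6P
SM[t]	C5H13N2O7P	2	28	48	0	6	[M+H]+,[M+Na]+	[M+HCOO]-	SM[d](30:1)	30	0	C35H73N2O7P
Cer[d]	HNO3	2	28	48	0	6	[M+H]+	[M-H]-	Cer[d](30:1)	30	1	C30H59NO3
Cer[t]	HNO4	2	28	48	0	6	[M+H]+	[M-H]-	Cer[d](30:1)	34	0	C34H69NO4
HexCer[d]	C6H11NO8	2	28	48	0	6	[M+H]+	[M-H]-	SM[d](30:1)	34	1	C40H77NO8
Hex2Cer[d]	C12H21NO13	2	28	48	0	6	[M+H]+	[M-H]-	SM[d](30:1)	34	1	C46H87NO13
SM4[d]	C6H11NO11S	2	28	48	0	6		[M-H]-	SM[d](30:1)	42	2	C48H91NO11S
SM4[t]	C6H11NO12S	2	28	48	0	6		[M-H]-	SM[d](30:1)	42	2	C48H91NO12S
GM1[d]	C37H61N3O31	2	30	44	0	6		[M-H]-	SM[d](30:1)	36	1	C73H131N3O31
GM2[d]	C31H51N3O26	2	30	44	0	6		[M-H]-	SM[d](30:1)	36	1	C67H121N3O26
GM3[d]	C23H38N2O21	2	30	44	0	6		[M-H]-	SM[d](30:1)	36	1	C59H108N2O21
TG	C3H2O6	3	36	80	0	16	[M+NH4]+,[M+Na]+		TG(42:0)	42	0	C45H86O6
CL	C9H14O17P2	4	48	72	0	8		[M-H]-	CL(56:0)	56	0	C65H126O17P2
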