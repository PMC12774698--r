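species	class_code	formula	nmol	ref_mass
CE(16:0)-d7	CE	C43H69D7O2	2.5	631.628469
PC(28:0)	PC	C36H72NO8P	2.0	677.499555
PE(28:0)	PE	C33H66NO8P	0.5	635.452605
PG(28:0)	PG	C34H67O10P	0.1	666.447185
PS(28:0)	PS	C34H66NO10P	5.0	679.442434
PA(28:0)	PA	C31H61O8P	0.5	592.410406
PI(16:0)	PI	C25H47O13P	0.5	586.275428
CL(56:0)	CL	C65H126O17P2	0.1	1240.847026
SM[d](30:1)	SM[d]	C35H71N2O6P	2.125	646.504975
Cer[d](30:1)	Cer[d]	C30H59NO3	0.125	481.449495
LPC(14:0)	LPC	C22H46NO7P	0.5	467.301189
LPE(14:0)	LPE	C19H40NO7P	0.1	425.254239
LPG(14:0)	LPG	C20H41O9P	0.02	456.248820
LPA(14:0)	LPA	C17H35O7P	0.1	382.212040
DG(28:0)	DG	C31H60O5	0.5	512.444075
TG(42:0)	TG	C45H86O6	0.5	722.642440
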