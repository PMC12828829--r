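class	backbone	carbon_increment	double_bond_decrement	default_oxygens	positive_adduct	negative_adduct	anchor_species	anchor_formula
CE	C27H44O2	CH2	H2	0	[M+H]+	none	CE 16:0	C43H76O2
Cer	HNO3	CH2	H2	2	[M+H-H2O]+	[M+CH3COO]-	Cer 34:1;O2	C34H67NO3
Chol	C27H46O	CH2	H2	0	[M+H]+	none	Chol	C27H46O
DG	C3H4O5	CH2	H2	0	[M+H]+	none	DG 34:1	C37H70O5
HexCer	C6H11NO8	CH2	H2	2	[M+H]+	[M+CH3COO]-	HexCer 34:1;O2	C40H77NO8
LPC	C8H18NO7P	CH2	H2	0	[M+H]+	[M+CH3COO]-	LPC 18:1	C26H52NO7P
LPE	C5H12NO7P	CH2	H2	0	[M+H]+	[M-H]-	LPE 18:1	C23H46NO7P
MG	C3H6O4	CH2	H2	0	[M+H]+	none	MG 18:1	C21H40O4
PC	C8H16NO8P	CH2	H2	0	[M+H]+	[M+CH3COO]-	PC 34:2	C42H80NO8P
PE	C5H10NO8P	CH2	H2	0	[M+H]+	[M-H]-	PE 34:1	C39H76NO8P
PG	C6H11O10P	CH2	H2	0	none	[M-H]-	PG 34:1	C40H77O10P
PI	C9H15O13P	CH2	H2	0	[M+NH4]+	[M-H]-	PI 38:4	C47H83O13P
PS	C6H10NO10P	CH2	H2	0	none	[M-H]-	PS 36:1	C42H80NO10P
SM	C5H13N2O6P	CH2	H2	2	[M+H]+	[M+CH3COO]-	SM 34:1;O2	C39H79N2O6P
TG	C3H2O6	CH2	H2	0	[M+H]+	none	TG 52:2	C55H102O6
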