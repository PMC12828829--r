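class_label	primary_is	primary_nmol_ml	primary_nmol_mg	secondary_is	secondary_nmol_ml	secondary_nmol_mg	quantitative
CE	CE 16:0 d7	64.1	0.26	CE 17:0	63.4	0.25	FALSE
Cer	Cer C18 d7	5.0	0.020	Cer 35:1	5.0	0.020	TRUE
Chol	Chol d7	914.4	3.77				FALSE
DG	DG 33:1 d7	2.5	0.010	DG 36:2 d5	2.6	0.010	FALSE
HexCer	GlcCer 36:1 d5	3.72	0.015	GlcCer 30:1	3.73	0.015	TRUE
LPC	LPC 18:1 d7	43.5	0.17	LPC 13:0	48.5	0.19	TRUE
LPE	LPE 18:1 d7	7.5	0.030	LPE 14:0	7.5	0.030	TRUE
MG	MG 18:1 d7	14.3	0.060	MG 19:1	15.1	0.057	FALSE
PC	PC 33:1 d7	562.2	2.25	PC 28:0	562.2	2.25	TRUE
PC O-	PC P-36:1 d9	50.0	0.20				TRUE
PE	PE 33:1 d7	224.9	0.90	PE 28:0	224.9	0.90	TRUE
PE O-	PE P-36:1 d9	219.2	0.88				TRUE
PG	PG 33:1 d7	8.7	0.035	PG 28:0	9.8	0.039	TRUE
PI	PI 33:1 d7	42.5	0.17	PI 33:1	42.9	0.17	TRUE
PS	PS 33:1 d7	85.7	0.34	PS 28:0	85.4	0.34	TRUE
SM	SM 36:2 d9	65.0	0.26	SM 30:1	64.9	0.26	TRUE
TG	TG 48:1 d7	164.0	0.66	TG 57:3	142.3	0.57	FALSE
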