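label	x	y	hemisphere	cluster
Fp1	-0.25	0.9	L	AT
Fp2	0.25	0.9	R	AT
AF7	-0.7	0.72	L	AT
AF3	-0.4	0.72	L	AT
AFz	0	0.72	Z	AT
AF4	0.4	0.72	R	AT
AF8	0.7	0.72	R	AT
F7	-0.85	0.54	L	AT
F5	-0.65	0.54	L	FR
F3	-0.45	0.54	L	FR
F1	-0.22	0.54	L	FR
Fz	0	0.54	Z	FR
F2	0.22	0.54	R	FR
F4	0.45	0.54	R	FR
F6	0.65	0.54	R	FR
F8	0.85	0.54	R	AT
FT7	-0.92	0.28	L	AT
FC5	-0.68	0.28	L	FR
FC3	-0.45	0.28	L	FR
FC1	-0.22	0.28	L	FR
FC2	0.22	0.28	R	FR
FC4	0.45	0.28	R	FR
FC6	0.68	0.28	R	FR
FT8	0.92	0.28	R	AT
T7	-1	0	L	PT
C5	-0.75	0	L	CE
C3	-0.5	0	L	CE
C1	-0.25	0	L	CE
Cz	0	0	Z	CE
C2	0.25	0	R	CE
C4	0.5	0	R	CE
C6	0.75	0	R	CE
T8	1	0	R	PT
TP7	-0.92	-0.28	L	PT
CP5	-0.68	-0.28	L	PT
CP3	-0.45	-0.28	L	CE
CP1	-0.22	-0.28	L	CE
CPz	0	-0.28	Z	CE
CP2	0.22	-0.28	R	CE
CP4	0.45	-0.28	R	CE
CP6	0.68	-0.28	R	PT
TP8	0.92	-0.28	R	PT
P7	-0.85	-0.54	L	PT
P5	-0.65	-0.54	L	P
P3	-0.45	-0.54	L	P
P1	-0.22	-0.54	L	P
Pz	0	-0.54	Z	P
P2	0.22	-0.54	R	P
P4	0.45	-0.54	R	P
P6	0.65	-0.54	R	P
P8	0.85	-0.54	R	PT
PO7	-0.7	-0.72	L	OC
PO3	-0.4	-0.72	L	OC
POz	0	-0.72	Z	OC
PO4	0.4	-0.72	R	OC
PO8	0.7	-0.72	R	OC
O1	-0.35	-0.9	L	OC
Oz	0	-0.9	Z	OC
O2	0.35	-0.9	R	OC
FT9	-1.05	0.3	L	AT
FT10	1.05	0.3	R	AT
Iz	0	-1	Z	OC
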