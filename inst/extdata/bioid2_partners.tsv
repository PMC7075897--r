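gene	protein_id	bait1_sham	bait1_20E	bait2_sham	bait2_20E	ctrl_sham	ctrl_20E
Nup358	A0A0B4K7J2	49	38	40	20	1	1
Nup50	Q7K0D8	18	19	13	6	1	0
Nup214	Q9W1X4	14	16	15	3	2	1
Nup88	Q9GYU8	6	6	12	4	2	0
Mor	A0A0B4JDA0	12	13	9	4	0	0
Chro	Q8T9D1	23	21	10	9	1	3
CP190	Q24478	15	12	9	4	0	0
Pzg	Q9VP57	18	18	10	5	0	0
Hcf	Q9V4C8	38	40	26	16	1	2
Uba1	Q8T0L3	29	23	6	2	0	0
scra	Q9V4P1	24	23	16	16	2	3
Dsh	P51140	17	15	13	8	0	0
Lam	P08928	16	17	14	5	0	0
NELF-A	Q86NP2	15	10	6	2	0	0
Dp1	Q7KN75	14	13	24	13	0	0
CtBP	O46036	11	6	5	2	0	0
cg10077	Q8MZI3	6	3	27	11	0	4
bel	Q9VHP0	6	2	22	4	4	6
CG14712	Q9VGL0	6	3	15	5	5	4
Rm62	P19109	5	2	11	4	0	0
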