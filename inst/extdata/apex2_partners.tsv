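gene	protein_id	bait1_sham	bait1_20E	bait2_sham	bait2_20E	ctrl_sham	ctrl_20E
Nup205	Q8IQV9	25	7	21	18	6	8
Nup88	Q9GYU8	11	5	21	22	3	6
Osa	A0A0B4KHB1	29	17	16	15	9	10
Mi-2	E1JI46	23	9	17	15	5	9
Brm	M9PFM5	21	1	58	3	5	10
kis	B7Z002	33	15	4	6	6	7
Mor	Q9VF03	31	18	12	12	12	12
CP190	Q24478	27	15	10	6	10	5
Pzg	Q9VP57	23	15	111	4	8	10
E(bx)	E1JHV6	37	12	6	2	8	10
RPII215	D0Z769	27	142	3	19	1	12
Hcf	Q9V4C8	29	20	29	32	8	10
Uba1	Q8T0L3	24	154	0	38	9	16
Ars2	A0A0B4KEI5	24	172	22	6	13	12
Sin3a	A0A0B4K765	24	12	15	12	7	8
Nipped-B	E1JGX3	24	6	8	10	1	5
l(3)72Ab	Q9VUV9	23	8	10	5	3	6
Prp8	A1Z8U0	23	5	6	3	4	4
Spt6	N0D8I3	23	2	6	8	1	2
RnrL	P48591	21	13	38	41	15	15
sle	Q8INM3	20	8	14	17	1	4
SMC2	Q7KK96	20	9	9	14	5	5
Scra	Q9V4P1	18	16	37	32	12	8
smid	P91638	15	6	21	17	4	7
CG4119	Q9V3Y5	15	5	17	22	4	7
hyd	A0A0B4LGZ6	14	7	24	22	4	6
Rpd3	Q94517	13	11	17	20	6	8
RanBPM	A0A0B4K851	12	3	17	20	4	7
HDAC4	Q9VYF3	11	33	9	35	6	12
Uba2	Q7KJV9	9	2	15	21	2	2
REG	Q9V3P3	9	71	21	3	6	6
CG10489	A9UND8	7	1	21	21	2	3
Mcm5	Q9VGW6	7	3	21	21	4	7
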