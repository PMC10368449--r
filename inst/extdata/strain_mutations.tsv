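# Mutation table for the 31 phage-resistant E. coli C strains (R2-R35;
# R1, R3, R15, R19 were excluded for lack of isogeneity or partial
# resistance and carry no rows here).  RECONSTRUCTED fixture: the
# strain-to-gene assignments, shared mutations (R8/R10, R27/R31,
# R4/R24/R29), effect spectrum (12 nonsense, 12 frameshift, 3 missense,
# 1 in-frame indel, 1 duplication, 3 IS insertions among 32 unique of 36
# total) and marker descriptors follow published statements; descriptors
# and positions not individually published are synthetic placeholders.
strain_id	gene	effect	descriptor	position	included
R2	waaW	is_insertion	S55_ins_IS4	55	TRUE
R4	waaO	frameshift	G152fsTer#163	152	TRUE
R5	gmhB	frameshift	A14fsTer#24	14	TRUE
R6	waaP	frameshift	S33fsTer#40	33	TRUE
R6	pssA	frameshift	L73fsTer#80	73	TRUE
R7	waaO	inframe_indel	D(T329-I330)	329	TRUE
R8	hldE	frameshift	T147fsTer#152	147	TRUE
R9	waaG	is_insertion	A118_ins_IS5	118	TRUE
R10	hldE	frameshift	T147fsTer#152	147	TRUE
R11	waaP	nonsense	W4Ter	4	TRUE
R12	waaF	nonsense	Q88Ter	88	TRUE
R13	waaO	nonsense	W161Ter	161	TRUE
R13	mdoG	frameshift	P211fsTer#215	211	TRUE
R14	waaF	frameshift	L160fsTer#170	160	TRUE
R16	galU	nonsense	Q141Ter	141	TRUE
R17	waaG	frameshift	D63fsTer#71	63	TRUE
R18	waaC	nonsense	W102Ter	102	TRUE
R20	waaO	frameshift	S99fsTer#112	99	TRUE
R20	yfjI	nonsense	Q34Ter	34	TRUE
R21	waaO	missense	P176L	176	TRUE
R22	galU	nonsense	W115Ter	115	TRUE
R23	waaG	nonsense	Y238Ter	238	TRUE
R24	waaO	frameshift	G152fsTer#163	152	TRUE
R25	rfaH	nonsense	Q54Ter	54	TRUE
R26	hldE	missense	D212G	212	TRUE
R27	hldE	missense	G27A	27	TRUE
R28	waaG	frameshift	L249fsTer#263	249	TRUE
R29	waaO	frameshift	G152fsTer#163	152	TRUE
R30	galU	frameshift	F29fsTer#35	29	TRUE
R31	hldE	missense	G27A	27	TRUE
R32	hldE	duplication	P242_A276dup(34)	242	TRUE
R33	waaT	is_insertion	V210_ins_IS5	210	TRUE
R34	waaW	nonsense	Q133Ter	133	TRUE
R35	waaG	nonsense	W42Ter	42	TRUE
R35	proA	nonsense	Q101Ter	101	TRUE
R35	wbbL	frameshift	G88fsTer#95	88	TRUE
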