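# Amino-acid changes in the 16 evolved phages that together reinfect all
# 31 resistant strains.  RECONSTRUCTED fixture: published changes are kept
# verbatim (Q154K/R at F position 154 in the phages evolved on the
# R8/R10/R18/R26 heptoseless hosts; Y103H (F) + A68T (H) additionally in
# the R8/R18 phages; G91V (H) reached by independent nucleotide changes in
# the R27/R31 phages; D116G/S (F) in four waaO-adapted phages; the
# parallel S427L (F); identical four-mutation genotypes for R22_T1/R28_T1;
# four mutations in every hard-resistance phage; R25_T4 lacks Q154K/R).
# Changes not individually published are synthetic, chosen so the totals
# match the published tallies: 40 records, 15 unique; 13 of 16 phages
# carry 2-4 changes.  Site numbering counts the initial Met.
phage_id	host_of_origin	transfer	protein	change	site
R8_T6	R8	6	F	Y103H	103
R8_T6	R8	6	F	Q154R	154
R8_T6	R8	6	H	A68T	68
R10_T6	R10	6	F	Q154K	154
R10_T6	R10	6	F	G425S	425
R18_T4	R18	4	F	Y103H	103
R18_T4	R18	4	F	Q154K	154
R18_T4	R18	4	H	A68T	68
R26_T1	R26	1	F	Q154R	154
R26_T1	R26	1	F	A333V	333
R27_T1	R27	1	H	G91V	91
R31_T1	R31	1	H	G91V	91
R4_T7	R4	7	H	A68T	68
R4_T7	R4	7	F	D116G	116
R4_T7	R4	7	F	S427L	427
R13_T6	R13	6	H	A68T	68
R13_T6	R13	6	F	D116S	116
R20_T5	R20	5	H	A68T	68
R20_T5	R20	5	F	D116G	116
R21_T1	R21	1	H	A68T	68
R21_T1	R21	1	F	D116S	116
R24_T1	R24	1	H	A68T	68
R24_T1	R24	1	F	A87T	87
R29_T1	R29	1	H	A68T	68
R22_T1	R22	1	F	Y103H	103
R22_T1	R22	1	F	Q154K	154
R22_T1	R22	1	F	S427L	427
R22_T1	R22	1	H	A68T	68
R28_T1	R28	1	F	Y103H	103
R28_T1	R28	1	F	Q154K	154
R28_T1	R28	1	F	S427L	427
R28_T1	R28	1	H	A68T	68
R6_T12	R6	12	F	G61D	61
R6_T12	R6	12	F	T363I	363
R6_T12	R6	12	H	G91V	91
R6_T12	R6	12	H	N57D	57
R25_T4	R25	4	F	Y103H	103
R25_T4	R25	4	F	D116S	116
R25_T4	R25	4	H	A68T	68
R25_T4	R25	4	H	A79V	79
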