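# Binary host x phage infection matrix (1 = sensitive, 0 = resistant).
# RECONSTRUCTED fixture: rows/columns pinned by published statements
# (identical R22_T1/R28_T1 infecting the eight galU/waaG-class hosts; the
# waaW pair infected by exactly R6_T12/R13_T6/R25_T4; near-identical
# 7/6-phage sets for the waaF pair; an identical 13-phage set for six of
# seven waaO hosts; R7 infected only by R26_T1 and later-experiment
# phages; heptoseless subgroups {R8,R10,R18,R26}, {R27,R31}, {R5}, {R32};
# WT infectivity lost exactly by the A68T+Q154K/R phages; R25_T4 the only
# phage infecting waaO hosts, the first heptoseless subgroup and WT).
# Cells not pinned by a published statement are synthetic, chosen once to
# be consistent with the published clustering description.
host_id,R8_T6,R10_T6,R18_T4,R26_T1,R27_T1,R31_T1,R4_T7,R13_T6,R20_T5,R21_T1,R24_T1,R29_T1,R22_T1,R28_T1,R6_T12,R25_T4,WT
R2,0,0,0,0,0,0,0,1,0,0,0,0,0,0,1,1,0
R4,1,0,1,0,1,1,1,1,1,1,1,1,1,1,0,1,0
R5,0,0,0,1,0,0,0,0,0,0,1,0,0,0,0,0,0
R6,0,0,0,0,0,0,0,0,0,0,0,0,0,0,1,0,0
R7,0,0,0,1,0,0,0,0,0,0,0,0,1,1,1,1,0
R8,1,1,1,1,0,0,0,0,0,0,0,0,1,1,0,1,0
R9,0,0,0,0,0,0,0,0,0,0,0,0,1,1,0,0,0
R10,1,1,1,1,0,0,0,0,0,0,0,0,1,1,0,1,0
R11,0,0,0,0,0,0,0,1,0,0,0,0,0,0,0,1,0
R12,1,1,1,1,0,0,0,0,0,0,0,0,1,1,1,0,0
R13,1,0,1,0,1,1,1,1,1,1,1,1,1,1,0,1,0
R14,1,1,0,1,0,0,0,0,0,0,0,0,1,1,1,0,0
R16,0,0,0,0,0,0,0,0,0,0,0,0,1,1,0,0,0
R17,0,0,0,0,0,0,0,0,0,0,0,0,1,1,0,0,0
R18,1,1,1,1,0,0,0,0,0,0,0,0,1,1,0,1,0
R20,1,0,1,0,1,1,1,1,1,1,1,1,1,1,0,1,0
R21,1,0,1,0,1,1,1,1,1,1,1,1,1,1,0,1,0
R22,0,0,0,0,0,0,0,0,0,0,0,0,1,1,0,0,0
R23,0,0,0,0,0,0,0,0,0,0,0,0,1,1,0,0,0
R24,1,0,1,0,1,1,1,1,1,1,1,1,1,1,0,1,0
R25,0,0,0,0,0,0,0,0,1,0,0,0,0,0,0,1,0
R26,1,1,1,1,0,0,0,0,0,0,0,0,1,1,0,1,0
R27,0,0,0,0,1,1,0,0,0,0,0,0,0,0,0,0,0
R28,0,0,0,0,0,0,0,0,0,0,0,0,1,1,0,0,0
R29,1,0,1,0,1,1,1,1,1,1,1,1,1,1,0,1,0
R30,0,0,0,0,0,0,0,0,0,0,0,0,1,1,0,0,0
R31,0,0,0,0,1,1,0,0,0,0,0,0,0,0,0,0,0
R32,0,0,0,0,0,0,0,0,0,1,0,0,0,0,0,0,0
R33,0,0,0,0,0,0,1,1,0,0,0,0,0,0,0,1,0
R34,0,0,0,0,0,0,0,1,0,0,0,0,0,0,1,1,0
R35,0,0,0,0,0,0,0,0,0,0,0,0,1,1,0,0,0
WT,0,1,0,1,1,1,1,1,1,1,1,1,0,0,1,1,1
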