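notation	bases	sequence	tm1	tm2	ta	ph_t
AC017019.1	28	CCCCCCTCCCCCCCTCCCCCCTCCCCCC	27.9	NA	18	7.1
AC018878.3	26	CCCCCACCCCCAGCCCCCTTTCCCCC	18.1	NA	7.5	7.1
ATXN2L	24	CCCCCCCCCCCCCCCCCCCCCCCC	23.7	NA	22.5	7
CAMK2G	50	CCCCCAGGCCCCGCCAGTCCCCCCCCCCGCCCGGCCCCCGGCCCGCCCCC	13	NA	11.3	6.9
DAP	29	CCCCCGCCCCCGCCCCCGCCCCCGCCCCC	24.7	NA	22	7
DRP2	70	CCCCCTCTTCCCCTCTCCCCCTCTCCCCCTCTCTCCCTCTTCCCCCTCTCCTTGTCTCCTTCTCTCCCCC	4.5	NA	6.5	6
DUX4L22	41	CCCCCGAAACGCGCCCCCCTCCCCCCTCCCCCCTCTCCCCC	29.2	NA	14.2	7.1
GH2	42	CCCCCACCCCCACCCCCATCCCCACGCCCCGCCCCCGCCCCC	22.7	NA	15.2	7.1
HIC2	74	CCCCCGGGACAGGGACCCTGGCCCCCCCCGACAGGCTGACGCCCACCCCCTCAAACTCTGGTGGACTTACCCCC	7.5	NA	7.8	6.4
HOXC10	24	CCCCCACCCCCACCCCCACCCCCC	17.7	NA	14	7.1
HOXD10	26	CCCCCCCCCCCTCCCCCGCGGCCCCC	10.2	NA	5.2	7.1
JAZF1	31	CCCCCCCCGCCCCCGCCCCCGCCCTCCCCCC	20.4	NA	18.5	7.1
MSMO1	23	CCCCCGCCCCCGCCCCCGCCCCC	16.6	NA	15.9	6.7
NFATC1	45	CCCCCGTTTCCCCCGCCAGCCCCAGCGCCCCCCTGCCCGGCCCCC	23.2	28.8	18.8	7.1
PIM1	45	CCCCCGACGCGCCCCCCAACACACAAACCCCCAGAATCCGCCCCC	29.4	NA	5.1	7
PLCB2	36	CCCCCGCCTCTTCTGGAGGCCCCCGCCCCCACCCCC	15	NA	13.2	7
QSOX1	25	CCCCCGCCCCCGAGCCCCCGCCCCC	20.1	NA	11.9	7.1
RAE1	116	CCCCCCGCCCCCCCCGCCCCCCCGCGCCGCCCCCCCCCGCCCCCCGCCCCCGTCCCCCCGCCCCCCCCGCCCCCCCCGCCCCCCGTCCCCCCGCCCCCCCGCCCCCCCGTCCCCCC	27.1	NA	13.6	6.8
RUNX1-1	31	CCCCCCCCGCACCCCTTCCCCCGGCCCCCCC	14.3	25	9.8	6.7
RUNX1-2	36	CCCCCCTCCCCCTGCCTCTCCCTCCCCCCTTTCCCC	13.2	24.4	10.1	6.5
RUNX1-3	32	CCCCCCTTTCCCCTGCCCCCCCTGCCTCCCCC	10.7	26.2	9.7	6.7
SHANK1b	28	CCCCCCTCCCCCCACCCCCCACCCCCCC	22.5	NA	12	7.1
SHANK3	80	CCCCCGCCTCCGGCGCAGCCCCCTCGCCACCCCCGCTTCCCTCCCGTCTCAGGCCCCCTCCCCCCGCCGCCCCCGCCCCC	18.3	NA	5.6	6.6
SHANK3b	79	CCCCCCGCACCGAGGCCTAGGACTCCCCCCCCCAACCCCGTCACAGCCCCCCAGACCCCCGCCCCGTGGCTCGGCCCCC	12.6	NA	4.8	6.5
SNORD112	36	CCCCCCCCCGCCCCCCACCCCCCCACCCCCCCCCCC	25.8	NA	15.9	7.2
SOX1	57	CCCCCTGCAGGCCCCCCTGCGCCTCCCCCCCCCCGCCACTGGCGCCTGGCTTCCCCC	9	NA	6.5	6.9
STX17	33	CCCCCGCCCCCGCCCCCGCCCCGCAGGGCCCCC	19.5	NA	15	7
LA16c-OS12.2	57	CCCCCCGTGTCGCTGTTCCCCCCGTGTCGCTGTTCCCCCCGTGTCGCTGTTCCCCCC	9.4	31.6	6.7	6.6
TRABD	23	CCCCCGCCCCCCCCCCCCCCCCC	21.3	NA	19.3	6.9
WNT7A	48	CCCCCGCCCCTCCCTCCTTTCCCCCGTCCCTCCCCCGCCCCCTCCCCC	22.7	NA	16.1	7.1
ZBTB7B	58	CCCCCCATCCCTCCCCTCCCTCCCCCCGCCCCTGCCACCCCCCAAACTCCCCCCCCCC	25.5	NA	10	7.1
ZFP41	52	CCCCCAGCCCCCGCCGACCCCCAGCTCCCGCCTCCGCCGACCCCCAGCCCCC	21.7	35.6	17.4	7
ZNF480	23	CCCCCGCCCCCGCCCCCGCCCCC	17.1	NA	15.2	6.7
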