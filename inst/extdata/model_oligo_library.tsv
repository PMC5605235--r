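notation	bases	sequence	tm1_ph55	tm2_ph55	ta_ph55	tm1_ph74	tm2_ph74	ta_ph74	ph_t
hTeloC	24	TAACCCTAACCCTAACCCTAACCC	43	NA	41	NA	NA	NA	6.5
C1T3	13	CTTTCTTTCTTTC	NA	NA	NA	NA	NA	NA	NA
C2T3	17	CCTTTCCTTTCCTTTCC	27.1	NA	26.2	NA	NA	NA	6.1
C3T3	21	CCCTTTCCCTTTCCCTTTCCC	46.3	NA	45.5	7	NA	6	6.7
C4T3	25	CCCCTTTCCCCTTTCCCCTTTCCCC	56.4	NA	55.6	15.8	NA	8.4	7.1
C5T3	29	CCCCCTTTCCCCCTTTCCCCCTTTCCCCC	61.4	NA	60.6	26.2	NA	6.7	7.2
C6T3	33	CCCCCCTTTCCCCCCTTTCCCCCCTTTCCCCCC	65.5	NA	63.6	9.1	31.3	9.7	6.8
C7T3	37	CCCCCCCTTTCCCCCCCTTTCCCCCCCTTTCCCCCCC	68.5	NA	64.7	12.8	32	8.7	7.4
C8T3	41	CCCCCCCCTTTCCCCCCCCTTTCCCCCCCCTTTCCCCCCCC	72.6	NA	64.7	18.8	35	13.8	7.1
C9T3	45	CCCCCCCCCTTTCCCCCCCCCTTTCCCCCCCCCTTTCCCCCCCCC	75.6	NA	65.7	20.8	35	12.1	7.3
C10T3	49	CCCCCCCCCCTTTCCCCCCCCCCTTTCCCCCCCCCCTTTCCCCCCCCCC	66	77	65	21.9	41.1	18.2	7.3
C5T1	23	CCCCCTCCCCCTCCCCCTCCCCC	60.6	NA	59.6	15.8	NA	14.1	6.9
C5T2	26	CCCCCTTCCCCCTTCCCCCTTCCCCC	60.6	NA	60.6	25.2	NA	16.1	7.1
C5T4	32	CCCCCTTTTCCCCCTTTTCCCCCTTTTCCCCC	63.3	NA	60.6	29.3	NA	5.3	6.7
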