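sample	selfing_generations	dosage_gy	mean_depth	n_indel	n_snp	family
2012BM7F223	7	8	28	25	56	
2012CM7F040P05	7	16	30	38	76	fam1
2012CM7F040P06	7	16	40	47	72	fam1
2012CM7F040P07	7	16	29	9	23	fam1
2012CM8F030P02	8	16	28	27	39	fam2
2012CM8F030P07	8	16	30	18	20	fam2
2012CM8F030P09	8	16	29	18	35	fam2
2012DM8F016P02	8	16	30	51	89	
4R30C22acr626MN13	6	16	20	34	41	
5R39C03Dr334cMN12	3	32	20	14	8	
FN0112228.06.02.01.M5	5	16	28	53	62	
FN0112885.02.06.03.M5	5	16	33	32	49	
FN0131633.06.01.M4	4	16	29	33	56	
FN0163764.04.01.M4	4	32	19	36	63	
FN0164160.03.02.01.01.M6	6	32	28	50	87	
FN0164472.x3.06.01.M5	5	32	29	49	83	
FN0170228.07.35.01.M5	5	16	25	38	64	
FN0170712.06.41.01.M5	5	16	29	41	80	
FN0171501.01.02.M4	4	32	31	38	67	
FN0172932.09.08.01.M5	5	16	24	15	16	
FN0173217.03.09.01.M5	5	16	30	25	56	
FN0175143.05.06.01.M5	5	16	32	34	45	
FN0175501.x2.02.01.M5	5	16	29	29	50	
FN0190069.01.01.M4	4	32	26	31	70	
R18C55Dhaar437MN13	6	32	20	23	25	
R52C55Dadr564MN13	5	32	18	20	22	
RP8DM5r597MN13	6	32	19	41	79	
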