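location	site_name	ratio1_printed	ratio2_printed	wt_reads_a	wt_reads_b	mutant_reads	site_class
4166537	intergenic(murI-rrsB)	415	587	41	29	17025	known
4035410	intergenic(hemG-rrsA)	314	925	53	18	16647	known
3311286	psrO	3782	3782	3	3	11347	known
2731278	intergenic(rrsG-clpB)	487	534	23	21	11206	known
223653	intergenic(gmhB-rrsH)	271	491	29	16	7853	known
3428875	intergenic(rrsD-yrdA)	340	234	20	29	6791	known
3943398	intergenic(rrsC-gltU)	1309	2619	4	2	5237	known
4209733	intergenic(rrsE-gltV)	4959	2480	1	2	4959	known
4168221	intergenic(rrsB-gltT)	123700	123700	0.01	0.01	1237	known
4168637	intergenic(gltT-rrlB)	120	419	7	2	837	known
3427176	intergenic(ileU-rrsD)	77500	775	0.01	1	775	known
3397879	yhdE	114	98	6	7	684	known
225355	intergenic(rrsH-ileV)	64300	643	0.01	1	643	known
4037115	intergenic(rrsA-ileT)	62600	62600	0.01	0.01	626	known
3318176	intergenic(rimP-metY)	102	609	6	1	609	known
4037523	rrlA	149	223	3	2	446	known
758515	sucA	30500	305	0.01	1	305	known
4207874	intergenic(purH-rrsE)	29000	290	0.01	1	290	known
3946623	intergenic(rrlC-rrfC)	22700	227	0.01	1	227	known
2729186	intergenic(rrlG-gltW)	55	221	4	1	221	known
4040443	intergenic(rrlA-rrfA)	20300	203	0.01	1	203	known
4212954	intergenic(rrlE-rrfE)	19500	65	0.01	3	195	known
3941526	intergenic(yieP-rrsC)	16200	41	0.01	4	162	known
4171559	intergenic(rrlB-rrfB)	12100	12100	0.01	0.01	121	known
3423873	intergenic(rrfD-rrlD)	11700	117	0.01	1	117	known
2726273	intergenic(rrfG-rrlG)	11500	58	0.01	2	115	known
122961	intergenic(pdhR-aceE)	6977	1550	2	9	13954	putative
639695	intergenic(ahpC-ahpF)	900	900	4	4	3598	putative
1799278	intergenic(pheM-rplT)	639	799	5	4	3196	putative
4330944	proP	66	83	15	12	992	putative
3889207	tnaA	301	129	3	7	903	putative
755579	sdhD	545	42	1	13	545	putative
3683389	dctA	74	74	7	7	518	putative
2171807	intergenic(gatR-gatD)	213	47	2	9	426	putative
3609652	yhhQ	58	77	4	3	231	putative
951147	intergenic(pflA-pflB)	15800	15800	0.01	0.01	158	putative
2351931	glpT	14300	143	0.01	1	143	putative
2237178	mglC	133	13300	1	0.01	133	putative
4307817	alsE	126	63	1	2	126	putative
2090031	hisL	11900	60	0.01	2	119	putative
1166043	intergenic(ycfP-ndh)	10800	10800	0.01	0.01	108	putative
159578	gluQ	10400	52	0.01	2	104	putative
444573	intergenic(panE-yajQ)	48	32	2	3	96	putative
1622816	intergenic(yneM-mgrR)	9100	91	0.01	1	91	putative
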