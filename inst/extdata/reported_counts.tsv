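# Published per-probe evaluation results against the SILVA SSU r138.1 RefNR
# and MiDAS 4.0 databases: targeted-hit counts, target-group sizes, and the
# coverage percentage as printed. Recomputing coverage from n_hit/n_group
# with coverage_percent() reproduces the printed value for all rows except
# the known internal inconsistencies (GAO431/GAO989 SILVA, Actino-658 SILVA,
# Bet135 SILVA), which the analysis flags.
probe	database	target_group	n_hit	n_group	printed_coverage_pct
Acc444	silva	Ca_Accumulibacter	18	86	20.9
HAcc466	silva	Ca_Accumulibacter	18	86	20.9
HAcc426	silva	Ca_Accumulibacter	26	86	30.2
Acc184	silva	Ca_Accumulibacter	8	86	9.3
CAcc184	silva	Ca_Accumulibacter	28	86	32.6
Acc119	silva	Ca_Accumulibacter	5	86	5.8
HAcc99	silva	Ca_Accumulibacter	33	86	38.4
HAcc139	silva	Ca_Accumulibacter	29	86	33.7
CAcc119	silva	Ca_Accumulibacter	17	86	19.8
Acc623	silva	Ca_Accumulibacter	5	86	5.8
Acc469	silva	Ca_Accumulibacter	1	86	1.2
Acc471	silva	Ca_Accumulibacter	27	86	31.4
Acc1011	silva	Ca_Accumulibacter	5	86	5.8
Acc635	silva	Ca_Accumulibacter	3	86	3.5
Acc470	silva	Ca_Accumulibacter	15	86	17.4
Acc471_2	silva	Ca_Accumulibacter	7	86	8.1
PAO846	silva	Ca_Accumulibacter	73	86	84.9
PAO462	silva	Ca_Accumulibacter	32	86	37.2
PAO651	silva	Ca_Accumulibacter	61	86	70.9
Acc444	midas	Ca_Accumulibacter	76	218	34.9
HAcc426	midas	Ca_Accumulibacter	92	218	42.2
Acc184	midas	Ca_Accumulibacter	32	218	14.7
CAcc184	midas	Ca_Accumulibacter	95	218	43.6
Acc119	midas	Ca_Accumulibacter	18	218	8.3
HAcc99	midas	Ca_Accumulibacter	111	218	50.9
HAcc139	midas	Ca_Accumulibacter	97	218	44.5
CAcc119	midas	Ca_Accumulibacter	18	218	8.3
Acc623	midas	Ca_Accumulibacter	1	218	0.5
Acc469	midas	Ca_Accumulibacter	2	218	0.9
Acc471	midas	Ca_Accumulibacter	40	218	18.3
Acc1011	midas	Ca_Accumulibacter	7	218	3.2
Acc635	midas	Ca_Accumulibacter	10	218	4.6
Acc470	midas	Ca_Accumulibacter	65	218	29.8
Acc471_2	midas	Ca_Accumulibacter	21	218	9.6
PAO846	midas	Ca_Accumulibacter	210	218	96.3
PAO462	midas	Ca_Accumulibacter	103	218	47.2
PAO651	midas	Ca_Accumulibacter	187	218	85.8
Tet2-174	silva	Tetrasphaera	4	51	7.8
Tet2-831	silva	Tetrasphaera	9	51	17.6
Tet2-842	silva	Tetrasphaera	10	51	19.6
Tet2-87	silva	Tetrasphaera	1	51	2.0
Tet3-654	silva	Tetrasphaera	1	51	2.0
Elo1-1250	silva	Tetrasphaera	10	51	19.6
Actino-221	silva	Tetrasphaera	1	51	2.0
Actino-1011	silva	Tetrasphaera	20	51	39.2
Tetra67	silva	Tetrasphaera	3	51	5.9
Tetra732	silva	Tetrasphaera	3	51	5.9
Tetra183	silva	Tetrasphaera	18	51	35.3
Tet2-174	midas	Tetrasphaera	12	157	7.6
Tet2-831	midas	Tetrasphaera	24	157	15.3
Tet2-842	midas	Tetrasphaera	37	157	23.6
Tet2-87	midas	Tetrasphaera	7	157	4.5
Elo1-1250	midas	Tetrasphaera	44	157	28.0
Actino-221	midas	Tetrasphaera	5	157	3.2
Actino-1011	midas	Tetrasphaera	65	157	41.4
Tetra67	midas	Tetrasphaera	35	157	22.3
Tetra732	midas	Tetrasphaera	15	157	9.6
Tetra183	midas	Tetrasphaera	92	157	58.6
Actino-658	silva	Ca_Phosphoribacter	15	28	60.0
Phos741	silva	Ca_Phosphoribacter	6	28	21.4
Phos601	silva	Ca_Phosphoribacter	6	28	21.4
Actino-658	midas	Ca_Phosphoribacter	26	74	35.1
Phos741	midas	Ca_Phosphoribacter	38	74	51.4
Phos601	midas	Ca_Phosphoribacter	7	74	9.5
Luti617	silva	Ca_Lutibacillus	3	5	60.0
Luti617	midas	Ca_Lutibacillus	5	15	33.3
TFO_DF862	silva	Defluviicoccus	4	75	5.3
TFO_DF618	silva	Defluviicoccus	4	75	5.3
TFO_DF218	silva	Defluviicoccus	7	75	9.3
DF1004	silva	Defluviicoccus	1	75	1.3
DF1013	silva	Defluviicoccus	1	75	1.3
DF198	silva	Defluviicoccus	3	75	4.0
DF181B	silva	Defluviicoccus	3	75	4.0
DF181A	silva	Defluviicoccus	1	75	1.3
DF1020	silva	Defluviicoccus	7	75	9.3
DF988	silva	Defluviicoccus	8	75	10.7
TFO_DF862	midas	Defluviicoccus	18	164	11.0
TFO_DF618	midas	Defluviicoccus	4	164	2.4
TFO_DF218	midas	Defluviicoccus	30	164	18.3
DF1004	midas	Defluviicoccus	4	164	2.4
DF1013	midas	Defluviicoccus	7	164	4.3
DF198	midas	Defluviicoccus	16	164	9.8
DF181B	midas	Defluviicoccus	8	164	4.9
DF181A	midas	Defluviicoccus	2	164	1.2
DF1020	midas	Defluviicoccus	38	164	23.2
DF988	midas	Defluviicoccus	29	164	17.7
DCMAG455	silva	Dechloromonas	6	181	3.3
DEMFE455	silva	Dechloromonas	40	181	22.1
Bet135	silva	Dechloromonas	16	181	8.9
Dech453	silva	Dechloromonas	5	181	2.8
Dech443	silva	Dechloromonas	6	181	3.3
DCMAG455	midas	Dechloromonas	25	387	6.5
DEMFE455	midas	Dechloromonas	83	387	21.4
Bet135	midas	Dechloromonas	60	387	15.5
Dech453	midas	Dechloromonas	3	387	0.8
Dech443	midas	Dechloromonas	31	387	8.0
CPB654	silva	Ca_Competibacter	83	95	87.4
GAO431	silva	Ca_Competibacter	48	95	57.0
GAO989	silva	Ca_Competibacter	50	95	59.0
CPB654	midas	Ca_Competibacter	388	429	90.4
GAO431	midas	Ca_Competibacter	219	429	51.0
GAO989	midas	Ca_Competibacter	215	429	50.1
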