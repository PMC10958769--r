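# FISH probes commonly used for PAO/GAO taxa in EBPR systems, with their
# published 5'->3' sequences, intended target group and formamide (FA%)
# hybridization stringency (metadata only; for FA ranges the lower bound is
# recorded). Tetra67 is the suspected corrected sequence: the originally
# published one may have dropped three internal bases.
name	sequence	role	target_group	formamide_pct	citation
Acc444	CCCAAGCAATTTCTTCCC	fish_probe	Ca_Accumulibacter	35	probeBase
HAcc466	CATCTACTCAGGGTATTAA	fish_probe	Ca_Accumulibacter	35	probeBase
HAcc426	CGCCGAAAGAGCTTTACA	fish_probe	Ca_Accumulibacter	35	probeBase
Acc184	GCTCCCAGAACGCAAGGT	fish_probe	Ca_Accumulibacter	35	probeBase
CAcc184	GCTCCCAGAGCGCAAGGT	fish_probe	Ca_Accumulibacter	35	probeBase
Acc119	GGATACGTTCCGATGCTT	fish_probe	Ca_Accumulibacter	35	probeBase
HAcc99	CTCACCCGTCCGCCACTC	fish_probe	Ca_Accumulibacter	35	probeBase
HAcc139	GCTACGTTATCCCCCACTC	fish_probe	Ca_Accumulibacter	35	probeBase
CAcc119	GGGCACGTTCCGATGCAT	fish_probe	Ca_Accumulibacter	35	probeBase
Acc623	CCAGCTGGACAGTCTCAA	fish_probe	Ca_Accumulibacter	35	probeBase
Acc469	CCAGGTACCGTCATCTACACAGGC	fish_probe	Ca_Accumulibacter	30	probeBase
Acc471	CTCCAGGTACCGTCATCTACACAG	fish_probe	Ca_Accumulibacter	40	probeBase
Acc1011	GCGAGCACTCCCAGATCTCTC	fish_probe	Ca_Accumulibacter	40	probeBase
Acc635	AACTCCAGCCTGGCAGTCTCAAAT	fish_probe	Ca_Accumulibacter	30	probeBase
Acc470	TTCGGGTACCGTCATCTACTCAGG	fish_probe	Ca_Accumulibacter	30	probeBase
Acc471_2	AGTCGGGTACCGTCATCTACACAG	fish_probe	Ca_Accumulibacter	30	probeBase
PAO846	GTTAGCTACGGCACTAAAAGG	fish_probe	Ca_Accumulibacter	35	probeBase
PAO462	CCGTCATCTACWCAGGGTATTAAC	fish_probe	Ca_Accumulibacter	35	probeBase
PAO651	CCCTCTGCCAAACTCCAG	fish_probe	Ca_Accumulibacter	35	probeBase
Tet1-266	CCCGTCGTCGCCTGTAGC	fish_probe	Tetrasphaera	25	probeBase
Tet2-174	GCTCCGTCTCGTATCCGG	fish_probe	Tetrasphaera	20	probeBase
Tet2-831	TCGTGAAATGAGTCCCAC	fish_probe	Tetrasphaera	10	probeBase
Tet2-842	GCGGCACAGAACTCGTGA	fish_probe	Tetrasphaera	30	probeBase
Tet2-87	TCGCCACTGATCAGGAGA	fish_probe	Tetrasphaera	10	probeBase
Tet2-892	TAGTTAGCCTTGCGGCCG	fish_probe	Tetrasphaera	5	probeBase
Tet3-19	CAGCGTTCGTCCTACACA	fish_probe	Tetrasphaera	0	probeBase
Tet3-654	GGTCTCCCCTACCATACT	fish_probe	Tetrasphaera	35	probeBase
Elo1-1250	CGCGATTTCGCAGCCCTT	fish_probe	Tetrasphaera	20	probeBase
Actino-221	CGCAGGTCCATCCCAGAC	fish_probe	Tetrasphaera	30	probeBase
Tet2-823	TGAGACCCGCACCTAGTT	fish_probe	Tetrasphaera	30	probeBase
Actino-1011	TTGCGGGGCACCCATCTCT	fish_probe	Tetrasphaera	30	probeBase
Tetra67	AGCAAGCTCCTCCGTCACCG	fish_probe	Tetrasphaera	40	probeBase
Tetra732	AGTGGTGGCCCAGAGACCTG	fish_probe	Tetrasphaera	40	probeBase
Tetra183	TAGAGATGCCTCTCCGTCTC	fish_probe	Tetrasphaera	30	probeBase
Actino-658	TCCGGTCTCCCCTACCAT	fish_probe	Ca_Phosphoribacter	40	probeBase
Phos741	TTCTCAGCGTCAGTTGTGGCCC	fish_probe	Ca_Phosphoribacter	30	probeBase
Phos601	GGTTGAGCCTCGGATTTTCACTGC	fish_probe	Ca_Phosphoribacter	30	probeBase
Luti617	CCCACTGCAAGTCCGGAATTGAGT	fish_probe	Ca_Lutibacillus	30	probeBase
TFO_DF862	AGCTAAGCTCCCCGACAT	fish_probe	Defluviicoccus	35	probeBase
TFO_DF618	GCCTCACTTGTCTAACCG	fish_probe	Defluviicoccus	25	probeBase
TFO_DF218	GAAGCCTTTGCCCCTCAG	fish_probe	Defluviicoccus	25	probeBase
DF1004	TAAGTTTCCTCAAGCCGC	fish_probe	Defluviicoccus	35	probeBase
DF1013	GAACTGAAGGCTCGAGTTTC	fish_probe	Defluviicoccus	35	probeBase
DF198	ATCCCAGGGCAACATAGTCT	fish_probe	Defluviicoccus	35	probeBase
DF181B	CTTTGCCCCTCAAGGCAC	fish_probe	Defluviicoccus	30	probeBase
DF181A	CTTTCCCTCACAAGGCAC	fish_probe	Defluviicoccus	30	probeBase
DF1020	CCGGCCGAACCGACTCCC	fish_probe	Defluviicoccus	35	probeBase
DF988	GATACGACGCCCATGTCAAGGG	fish_probe	Defluviicoccus	35	probeBase
DCMAG455	CAGGTATTAGCTGATGCG	fish_probe	Dechloromonas	30	probeBase
DEMFE455	AGGGTATTAACCCATGCG	fish_probe	Dechloromonas	30	probeBase
Bet135	ACGTTATCCCCCACTCAATGG	fish_probe	Dechloromonas	45	probeBase
Dech453	GGGTATTCACCCATGCGA	fish_probe	Dechloromonas	35	probeBase
Dech443	ACCCATGCATTTTCTTCCCGG	fish_probe	Dechloromonas	35	probeBase
CPB654	TCCTCTAGCCCACTC	fish_probe	Ca_Competibacter	35	probeBase
GAO431	TCCCCGCCTAAAGGGCTT	fish_probe	Ca_Competibacter	35	probeBase
GAO989	TTCCCCGGATGTCAAGGC	fish_probe	Ca_Competibacter	35	probeBase
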