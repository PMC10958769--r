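# Universal 16S rRNA gene primers. 27Fp (the non-degenerate 27F'), 534R,
# 515F and 926R carry the sequences printed in the source methods; the
# remaining primers use their standard published sequences from the primer
# literature. All 5'->3'.
name	sequence	role	target_group	formamide_pct	citation
27F	AGRGTTTGATYMTGGCTCAG	primer_forward	universal	NA	literature
27Fp	AGAGTTTGATCCTGGCTCAG	primer_forward	universal	NA	methods
338F	ACTCCTACGGGAGGCAGCAG	primer_forward	universal	NA	literature
341F	CCTACGGGNGGCWGCAG	primer_forward	universal	NA	literature
515F	GTGYCAGCMGCCGCGGTAA	primer_forward	universal	NA	methods
520F	AYTGGGYDTAAAGNG	primer_forward	universal	NA	literature
799F	AACMGGATTAGATACCCKG	primer_forward	universal	NA	literature
533R	TTACCGCGGCTGCTGGCAC	primer_reverse	universal	NA	literature
534R	TTACCGCGGCTGCTGGCAC	primer_reverse	universal	NA	methods
802R	TACNVGGGTATCTAATCC	primer_reverse	universal	NA	literature
806R	GGACTACHVGGGTWTCTAAT	primer_reverse	universal	NA	literature
907R	CCGTCAATTCMTTTRAGTTT	primer_reverse	universal	NA	literature
926R	CCGYCAATTYMTTTRAGTTT	primer_reverse	universal	NA	methods
1193R	ACGTCATCCCCACCTTCC	primer_reverse	universal	NA	literature
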