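# Universal primer sets and the 16S hypervariable regions they span.
# anchored_5prime marks 27F-type sets whose forward primer anneals at the
# very 5' end of the gene and is therefore subject to the truncation
# omission rule. Length bounds are generous brackets around the expected
# amplicon for each region.
name	forward	reverse	region	min_len	max_len	anchored_5prime
27F-533R	27F	533R	V1-V3	300	800	TRUE
27F-534R	27F	534R	V1-V3	300	800	TRUE
27Fp-533R	27Fp	533R	V1-V3	300	800	TRUE
27Fp-534R	27Fp	534R	V1-V3	300	800	TRUE
338F-806R	338F	806R	V3-V4	250	700	FALSE
341F-806R	341F	806R	V3-V4	250	700	FALSE
520F-802R	520F	802R	V4	150	500	FALSE
515F-806R	515F	806R	V4	150	500	FALSE
515F-907R	515F	907R	V4-V5	250	600	FALSE
515F-926R	515F	926R	V4-V5	250	600	FALSE
799F-1193R	799F	1193R	V5-V7	250	600	FALSE
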