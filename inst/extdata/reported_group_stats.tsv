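# Published group-level statistics: probe-mix union coverage and
# blind-spot (uncovered-by-any-probe) tallies, with the numerator and
# denominator each statement rests on. mix_coverage rows: numerator =
# sequences covered by the mix; uncovered rows: numerator = sequences hit
# by no evaluated probe.
label	database	target_group	kind	numerator	denominator	printed_pct
PAOmix	silva	Ca_Accumulibacter	mix_coverage	79	86	91.9
PAOmix	midas	Ca_Accumulibacter	mix_coverage	211	218	96.8
GAO431+GAO989	silva	Ca_Competibacter	mix_coverage	62	95	65.3
CPB654_family	silva	Ca_Competibacteraceae	mix_coverage	105	118	89.0
all_defluviicoccus_probes	midas	Defluviicoccus	mix_coverage	93	164	56.7
uncovered_by_any_probe	silva	Ca_Accumulibacter	uncovered	3	86	3.5
uncovered_by_any_probe	midas	Ca_Accumulibacter	uncovered	3	218	1.4
uncovered_by_any_probe	silva	Tetrasphaera	uncovered	14	51	27.5
uncovered_by_any_probe	midas	Tetrasphaera	uncovered	23	157	14.6
uncovered_by_any_probe	midas	Dechloromonas	uncovered	209	387	54.0
uncovered_by_any_probe	midas	Defluviicoccus	uncovered	71	164	43.3
uncovered_by_any_probe	midas	Ca_Competibacter	uncovered	41	429	9.6
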