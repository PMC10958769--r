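Package: oligocover
Title: In Silico Coverage and Specificity of FISH Probes and 16S rRNA Primers
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Evaluates oligonucleotide probes and degenerate PCR primer sets
    against taxonomically annotated 16S rRNA reference databases. Implements
    IUPAC-aware, mismatch-bounded scanning of probes and primers, in-silico
    PCR amplicon prediction, per-taxon coverage and specificity statistics
    (including probe-mix union coverage, Venn partitions and blind-spot
    extraction), greedy identity clustering and reference-anchored taxonomy
    refinement, 16S copy-number abundance correction, and a synthetic
    reference-database generator with planted, machine-checkable ground
    truth. Motivated by the evaluation of probes and universal primers for
    polyphosphate- and glycogen-accumulating organisms in enhanced
    biological phosphorus removal systems.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Biostrings,
    jsonlite,
    yaml,
    methods,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    BiocGenerics
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
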