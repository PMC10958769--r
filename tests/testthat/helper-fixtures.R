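# Shared fixtures built in code.

fixture_probes <- function() {
  data.frame(
    name = c("PAO651", "PAO846", "Dech443"),
    sequence = c("CCCTCTGCCAAACTCCAG", "GTTAGCTACGGCACTAAAAGG",
                 "ACCCATGCATTTTCTTCCCGG"),
    role = "fish_probe",
    target_group = c("Ca_Accumulibacter", "Ca_Accumulibacter",
                     "Dechloromonas"),
    stringsAsFactors = FALSE
  )
}

fixture_primer_sets <- function(sets = c("515F-926R", "27F-534R")) {
  po <- parse_oligo_table(system.file("extdata", "primer_oligos.tsv",
                                      package = "oligocover"))
  pp <- read.delim(system.file("extdata", "primer_pairs.tsv",
                               package = "oligocover"),
                   comment.char = "#", stringsAsFactors = FALSE)
  build_primer_sets(po, pp)[sets]
}

# small planted database: 3 taxa, known binder/amplicon truth
fixture_synthetic <- function(seed = 1, frac_truncated = 0,
                              frac_n = 0, taxa = c(Ca_Accumulibacter = 10,
                                                   Dechloromonas = 8,
                                                   Thauera = 7)) {
  cfg <- synthetic_db_config(
    taxa = taxa,
    probes = fixture_probes(),
    probe_plant = data.frame(
      oligo = c("PAO651", "PAO846", "Dech443", "PAO846"),
      taxon = c("Ca_Accumulibacter", "Ca_Accumulibacter", "Dechloromonas",
                "Dechloromonas"),
      n = c(7, 9, 6, 2)),
    primer_sets = fixture_primer_sets(),
    primer_plant = data.frame(
      set = rep(c("515F-926R", "27F-534R"), 3),
      taxon = rep(names(taxa)[1:3], each = 2),
      prob = 1),
    frac_n = frac_n, frac_truncated = frac_truncated)
  suppressMessages(generate_synthetic_db(cfg, seed = seed))
}

# a tiny hand-built database where binding is fully known by construction:
# probe sites are spliced literally into otherwise site-free backbones
fixture_handmade_db <- function() {
  pad <- function(n, base = "A") strrep(base, n)
  site1 <- "CTGGAGTTTGGCAGAGGG"        # revcomp of PAO651
  site2 <- "CCTTTTAGTGCCGTAGCTAAC"     # revcomp of PAO846
  seqs <- c(
    s1 = paste0(pad(40), site1, pad(40)),
    s2 = paste0(pad(30), site1, pad(20, "C"), site2, pad(30)),
    s3 = paste0(pad(40), site2, pad(40)),
    s4 = paste0(pad(50), pad(50, "G"))
  )
  ref_db(names(seqs), seqs,
         taxonomy = list(c("Bacteria", "Gx"), c("Bacteria", "Gx"),
                         c("Bacteria", "Gx"), c("Bacteria", "Gy")),
         source_db = "handmade")
}

quiet_group <- function(...) suppressMessages(build_target_group(...))

# on-disk fixture + run config for the orchestration layer
pipeline_fixture <- function(dir, seed = 7, frac_truncated = 0.2) {
  g <- fixture_synthetic(seed = seed, frac_truncated = frac_truncated)
  db_path <- file.path(dir, "db.fasta")
  write_fasta(g$db, db_path)
  oligos <- rbind(
    cbind(fixture_probes(), formamide_pct = 35, citation = "fixture"),
    parse_oligo_table(system.file("extdata", "primer_oligos.tsv",
                                  package = "oligocover")))
  oligo_path <- file.path(dir, "oligos.tsv")
  write.table(oligos, oligo_path, sep = "\t", row.names = FALSE,
              quote = FALSE)
  list(
    truth = g$truth, db = g$db,
    config = list(
      databases = list(list(path = db_path, dialect = "plain",
                            tag = "synthetic", mode_27f = "apply_rule")),
      oligo_table = oligo_path,
      primer_pairs = system.file("extdata", "primer_pairs.tsv",
                                 package = "oligocover"),
      groups = list(
        list(name = "Ca_Accumulibacter", predicate = "Ca_Accumulibacter"),
        list(name = "Dechloromonas", predicate = "Dechloromonas")),
      mixes = list(PAOmix_fixture = c("PAO651", "PAO846")),
      out_dir = file.path(dir, "out"),
      seed = seed))
}

dir_digest <- function(dir) {
  files <- sort(list.files(dir, recursive = TRUE, full.names = TRUE))
  setNames(tools::md5sum(files), basename(files))
}
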