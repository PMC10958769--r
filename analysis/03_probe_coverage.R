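#!/usr/bin/env Rscript
# Probe coverage/specificity evaluation on the synthetic study database:
# per-probe reports, PAOmix union coverage, Venn co-coverage partition, and
# blind-spot exports, then a verification pass against the generator truth.
# Requires analysis/02_simulate_reference_db.R to have been run.

library(oligocover)
library(jsonlite)

stopifnot(file.exists("results/synthetic/db.fasta"))
truth <- read_json("results/synthetic/truth.json", simplifyVector = TRUE)

config <- list(
  databases = list(list(path = "results/synthetic/db.fasta",
                        dialect = "plain", tag = "synthetic",
                        mode_27f = "apply_rule")),
  oligo_table = "results/synthetic/oligos.tsv",
  groups = list(
    list(name = "Ca_Accumulibacter", predicate = "Ca_Accumulibacter"),
    list(name = "Dechloromonas", predicate = "Dechloromonas"),
    list(name = "Ca_Competibacter", predicate = "Ca_Competibacter")),
  mixes = list(PAOmix = c("PAO462", "PAO651", "PAO846")),
  out_dir = "results/probe_eval",
  seed = 1L)

reports <- run_probe_eval(config)
tab <- coverage_report_table(reports)
cat("\nprobe coverage on the synthetic database:\n")
print(tab[tab$oligo_or_mix %in% c("PAO846", "PAO651", "PAO462", "PAOmix") &
            tab$target_group == "Ca_Accumulibacter",
          c("oligo_or_mix", "n_target", "n_target_hit", "coverage_pct",
            "n_nontarget_hit")])

# verification against planted truth
member <- unlist(truth$clade_membership)
acc_ids <- names(member)[member == "Ca_Accumulibacter"]
for (p in c("PAO846", "PAO651", "PAO462")) {
  row <- tab[tab$oligo_or_mix == p & tab$target_group == "Ca_Accumulibacter", ]
  want <- length(intersect(truth$planted_binders[[p]], acc_ids))
  stopifnot(row$n_target_hit == want)
}
mix_row <- tab[tab$oligo_or_mix == "PAOmix" &
                 tab$target_group == "Ca_Accumulibacter", ]
union_ids <- intersect(Reduce(union, truth$planted_binders[
  c("PAO846", "PAO651", "PAO462")]), acc_ids)
stopifnot(mix_row$n_target_hit == length(union_ids))
cat("\nall probe reports agree exactly with the planted truth\n")
cat("outputs under results/probe_eval/\n")
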