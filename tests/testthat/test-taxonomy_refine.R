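test_that("pairwise identity matches the textbook alignment oracle", {
  expect_equal(pairwise_identity("ACGTACGTAC", "ACGTACGTAT"), 0.9)
  expect_equal(pairwise_identity("ACGTACGT", "ACGTACGT"), 1.0)
  set.seed(101)
  for (i in 1:15) {
    a <- random_subject(sample(50:120, 1), p_n = 0, p_ambig = 0)
    b <- if (i %% 3 == 0) {
      random_subject(sample(50:120, 1), p_n = 0, p_ambig = 0)
    } else {
      # related pair, possibly with an indel
      bb <- mutate_from_reference(a, runif(1, 0, 0.1))
      if (i %% 2 == 0) {
        cut <- sample(nchar(bb) - 10, 1)
        bb <- paste0(substr(bb, 1, cut),
                     substr(bb, cut + sample(1:3, 1), nchar(bb)))
      }
      bb
    }
    expect_equal(pairwise_identity(a, b), oracle_identity(a, b))
  }
})

test_that("greedy clustering reproduces the identity-matrix oracle at both cut-offs", {
  set.seed(111)
  base <- random_subject(300, p_n = 0, p_ambig = 0)
  seqs <- c(
    s1 = base,
    s2 = base,                                    # exact copy
    s3 = mutate_from_reference(base, 0.05)        # ~95% identity
  )
  cl987 <- greedy_cluster(seqs, 0.987)
  expect_equal(length(unique(cl987$cluster_id)), 2)
  expect_setequal(cl987$seq_id[cl987$cluster_id ==
                                 cl987$cluster_id[cl987$seq_id == "s1"]],
                  c("s1", "s2"))
  cl945 <- greedy_cluster(seqs, 0.945)
  expect_equal(length(unique(cl945$cluster_id)), 1)
  single <- greedy_cluster(c(only = base), 0.987)
  expect_equal(nrow(single), 1)
  expect_equal(single$centroid_id, "only")

  # larger synthetic sets vs the independently derived greedy assignment
  for (cutoff in c(0.987, 0.945)) {
    pool <- list()
    for (k in 1:5) {
      anc <- random_subject(sample(250:350, 1), p_n = 0, p_ambig = 0)
      for (j in 1:8) {
        pool[[sprintf("t%d_%d", k, j)]] <-
          mutate_from_reference(anc, runif(1, 0, 0.012))
      }
    }
    seqs <- unlist(pool)
    got <- greedy_cluster(seqs, cutoff)
    want <- oracle_greedy_cluster(seqs, cutoff, pairwise_identity)
    expect_identical(setNames(got$centroid_id, got$seq_id)[names(want)],
                     want)
    # cut-off invariant: every member reaches its centroid
    expect_true(all(got$identity_to_centroid >= cutoff))
    expect_true(all(got$identity_to_centroid[got$seq_id ==
                                               got$centroid_id] == 1))
    # deterministic
    expect_identical(got, greedy_cluster(seqs, cutoff))
  }
})

test_that("nearest-reference assignment recovers planted labels and abstains below threshold", {
  set.seed(121)
  refs <- c(Ca_Accumulibacter = random_subject(400, p_n = 0, p_ambig = 0),
            Dechloromonas = random_subject(400, p_n = 0, p_ambig = 0),
            Tetrasphaera = random_subject(400, p_n = 0, p_ambig = 0))
  ref_seqs <- setNames(unname(refs), paste0("ref_", names(refs)))
  labels <- setNames(names(refs), names(ref_seqs))

  hit <- assign_by_reference(refs[["Ca_Accumulibacter"]], ref_seqs, labels)
  expect_equal(hit$label, "Ca_Accumulibacter")
  expect_equal(hit$identity, 1.0)

  far <- assign_by_reference(mutate_from_reference(refs[[1]], 0.10),
                             ref_seqs, labels, min_identity = 0.945)
  expect_equal(far$label, "unassigned")
  # monotone abstention: lowering the threshold returns the same label
  relaxed <- assign_by_reference(mutate_from_reference(refs[[1]], 0.10),
                                 ref_seqs, labels, min_identity = 0)
  expect_equal(relaxed$best_ref, far$best_ref)

  # planted 2% mutants are recovered perfectly
  recovered <- vapply(1:30, function(i) {
    truth <- sample(names(refs), 1)
    q <- mutate_from_reference(refs[[truth]], 0.02)
    assign_by_reference(q, ref_seqs, labels)$label == truth
  }, logical(1))
  expect_true(all(recovered))
})

test_that("reference anchoring rebuilds planted clade memberships as explicit groups", {
  # no planted oligo sites here: site planting at per-sequence random
  # positions adds apparent divergence that has nothing to do with clade
  # structure, so taxonomy refinement is exercised on a clean phylogeny
  cfg <- synthetic_db_config(
    taxa = c(Ca_Accumulibacter = 8, Dechloromonas = 8, Thauera = 7),
    len_range = c(600L, 800L))
  g <- suppressMessages(generate_synthetic_db(cfg, seed = 131))
  # anchor on one representative per taxon drawn from the database itself
  member <- unlist(g$truth$clade_membership)
  rep_ids <- vapply(unique(member), function(tx) {
    names(member)[member == tx][1]
  }, character(1))
  refs <- setNames(g$db$seqs$sequence[match(rep_ids, g$db$seqs$id)], rep_ids)
  labels <- setNames(names(rep_ids), rep_ids)
  grp <- suppressMessages(
    refine_target_group(g$db, refs, labels, taxon = "Dechloromonas"))
  expect_setequal(grp$ids, names(member)[member == "Dechloromonas"])
})
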