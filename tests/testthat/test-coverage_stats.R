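test_that("coverage percentage uses round-half-up at one decimal", {
  expect_equal(coverage_percent(73, 86), 84.9)
  expect_equal(coverage_percent(209, 387), 54.0)
  expect_equal(coverage_percent(0, 5), 0.0)
  expect_equal(coverage_percent(1, 16), 6.3)   # 6.25 rounds up
  expect_true(is.na(coverage_percent(0, 0)))   # undefined, not 0
})

test_that("target groups resolve by predicate at any rank or by explicit ids", {
  g <- fixture_synthetic(seed = 2)
  grp <- quiet_group(g$db, predicate = "Dechloromonas")
  expect_setequal(grp$ids,
                  names(which(unlist(g$truth$clade_membership) ==
                              "Dechloromonas")))
  grp2 <- quiet_group(g$db, ids = g$db$seqs$id[1:3])
  expect_equal(length(grp2$ids), 3)
  expect_error(quiet_group(g$db, ids = "no_such_id"), "not in database")
  expect_warning(build_target_group(g$db, predicate = "Nitrospira"),
                 "empty target group")
})

test_that("single-oligo coverage matches planted truth including non-target hits", {
  g <- fixture_synthetic(seed = 13)
  acc <- quiet_group(g$db, predicate = "Ca_Accumulibacter")
  r <- evaluate_oligo_coverage(fixture_probes()[2, ], g$db, acc)  # PAO846
  truth <- g$truth$planted_binders$PAO846
  expect_equal(r$n_target_hit, 9)
  expect_equal(r$coverage_pct, 90.0)
  expect_equal(sum(r$nontarget_hits), 2)          # planted out-group hits
  expect_equal(unname(r$nontarget_hits["Dechloromonas"]), 2L)
  expect_setequal(r$uncovered_ids, setdiff(acc$ids, truth))

  none <- evaluate_oligo_coverage(
    list(sequence = "TTTTTTTTTTTTTTTTTT", role = "fish_probe"), g$db, acc)
  expect_equal(none$coverage_pct, 0.0)
  expect_setequal(none$uncovered_ids, acc$ids)
})

test_that("mix coverage is the set union and never below any member", {
  db <- fixture_handmade_db()
  grp <- quiet_group(db, predicate = "Gx")
  probes <- fixture_probes()[1:2, ]
  r1 <- evaluate_oligo_coverage(probes[1, ], db, grp)  # binds s1, s2
  r2 <- evaluate_oligo_coverage(probes[2, ], db, grp)  # binds s2, s3
  mix <- evaluate_mix_coverage(probes, db, grp, mix_name = "mix")
  expect_equal(r1$n_target_hit, 2)
  expect_equal(r2$n_target_hit, 2)
  expect_equal(mix$n_target_hit, 3)
  expect_equal(mix$coverage_pct, 100.0)
  expect_gte(mix$coverage_pct, max(r1$coverage_pct, r2$coverage_pct))
  single <- evaluate_mix_coverage(probes[1, ], db, grp, mix_name = "PAO651")
  expect_equal(single$n_target_hit, r1$n_target_hit)
  expect_identical(single$uncovered_ids, r1$uncovered_ids)
})

test_that("Venn partition is disjoint, sums to the group, reproduces marginals", {
  db <- fixture_handmade_db()
  # group of 4 including the never-hit s4
  grp <- quiet_group(db, ids = db$seqs$id)
  probes <- fixture_probes()[1:2, ]
  vp <- co_coverage_partition(probes, db, grp)
  counts <- setNames(vp$count, vp$signature)
  expect_equal(unname(counts["none"]), 1L)
  expect_equal(unname(counts["PAO651"]), 1L)
  expect_equal(unname(counts["PAO846"]), 1L)
  expect_equal(unname(counts["PAO651+PAO846"]), 1L)
  expect_equal(sum(vp$count), 4)

  g <- fixture_synthetic(seed = 17)
  acc <- quiet_group(g$db, predicate = "Ca_Accumulibacter")
  vp2 <- co_coverage_partition(fixture_probes()[1:2, ], g$db, acc)
  expect_equal(sum(vp2$count), length(acc$ids))
  # marginal sums reproduce per-probe targeted hits
  for (p in c("PAO651", "PAO846")) {
    marginal <- sum(vp2$count[grepl(p, vp2$signature, fixed = TRUE)])
    expect_equal(marginal,
                 length(intersect(g$truth$planted_binders[[p]], acc$ids)))
  }
  expect_error(co_coverage_partition(
    lapply(1:7, function(i) list(sequence = strrep("ACGT", 5),
                                 role = "fish_probe", name = paste0("p", i))),
    db, grp), "more than 6")
})

test_that("blind-spot extraction returns exactly the planted non-binders", {
  g <- fixture_synthetic(seed = 19)
  acc <- quiet_group(g$db, predicate = "Ca_Accumulibacter")
  probes <- fixture_probes()[1:2, ]
  covered <- union(g$truth$planted_binders$PAO651,
                   g$truth$planted_binders$PAO846)
  unc <- extract_uncovered(probes, g$db, acc)
  expect_identical(unc, sort(setdiff(acc$ids, covered)))
  expect_identical(extract_uncovered(probes[0, ], g$db, acc), sort(acc$ids))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_uncovered(g$db, unc, f)
  tb <- read.delim(f)
  expect_equal(tb$id, unc)
  expect_true(all(grepl("Ca_Accumulibacter", tb$taxonomy)))
})

test_that("statistics are invariant under database record order", {
  g <- fixture_synthetic(seed = 23)
  perm <- sample(length(g$db))
  db2 <- ref_db(g$db$seqs$id[perm], g$db$seqs$sequence[perm],
                g$db$taxonomy[perm], source_db = "synthetic")
  for (p in seq_len(2)) {
    grp1 <- quiet_group(g$db, predicate = "Ca_Accumulibacter")
    grp2 <- quiet_group(db2, predicate = "Ca_Accumulibacter")
    r1 <- evaluate_oligo_coverage(fixture_probes()[p, ], g$db, grp1)
    r2 <- evaluate_oligo_coverage(fixture_probes()[p, ], db2, grp2)
    expect_equal(r1$coverage_pct, r2$coverage_pct)
    expect_identical(r1$uncovered_ids, r2$uncovered_ids)
    expect_identical(r1$nontarget_hits, r2$nontarget_hits)
  }
})

test_that("copy-number correction renormalizes abundance/copies to the simplex", {
  expect_equal(copy_number_correct(c(a = 0.5, b = 0.5), c(a = 2, b = 4)),
               c(a = 2 / 3, b = 1 / 3))
  x <- c(a = 0.2, b = 0.3, c = 0.5)
  expect_equal(copy_number_correct(x, c(a = 3, b = 3, c = 3)), x)
  # Accumulibacter-like 2 copies, Tetrasphaera-like 1, Dechloromonas-like 4
  corr <- copy_number_correct(
    c(acc = 1 / 3, tet = 1 / 3, dech = 1 / 3),
    c(acc = 2, tet = 1, dech = 4))
  expect_equal(unname(corr), c(2 / 7, 4 / 7, 1 / 7), tolerance = 1e-12)
  expect_equal(sum(corr), 1)
  # invariant to uniform scaling of copy numbers
  expect_equal(copy_number_correct(x, c(a = 1, b = 2, c = 4)),
               copy_number_correct(x, c(a = 10, b = 20, c = 40)))
  expect_error(copy_number_correct(c(a = 1), c(b = 2)), "missing 16S copy")
})
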