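test_that("reverse complement follows the IUPAC table and is an involution", {
  expect_equal(reverse_complement("ACGT"), "ACGT")
  expect_equal(reverse_complement("N"), "N")
  expect_equal(reverse_complement("CCGYCAATTYMTTTRAGTTT"),
               "AAACTYAAAKRAATTGRCGG")
  expect_error(reverse_complement("ACGX"), "non-IUPAC")
  set.seed(21)
  for (i in 1:50) {
    s <- random_oligo(sample(5:40, 1), p_ambig = 0.4)
    expect_identical(reverse_complement(reverse_complement(s)), s)
  }
})

test_that("per-position semantics: subject subset matches, N consumes its own allowance", {
  expect_equal(mismatches_at("GTGYCAG", "GTGTCAG", 0),
               list(mismatches = 0, n_positions = 0))
  expect_equal(mismatches_at("GTGYCAG", "GTGNCAG", 0),
               list(mismatches = 0, n_positions = 1))
  expect_equal(mismatches_at("GTGYCAG", "GTGACAG", 0),
               list(mismatches = 1, n_positions = 0))
  # oligo N accepts any concrete base, but a subject N is still only an N
  expect_equal(mismatches_at("NNNN", "ACGT", 0)$mismatches, 0)
  expect_equal(mismatches_at("NNNN", "ACNT", 0)$n_positions, 1)
})

test_that("probe scanning finds planted sites and respects the budget", {
  set.seed(31)
  flank <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                             collapse = "")
  site <- reverse_complement("CCCTCTGCCAAACTCCAG")  # PAO651
  subj <- paste0(flank(50), site, flank(50))
  hits <- scan_oligo("CCCTCTGCCAAACTCCAG", subj)
  expect_equal(hits$start, 50)
  expect_equal(hits$mismatches, 0)

  ch <- strsplit(subj, "")[[1]]
  ch[55] <- setdiff(c("A", "C", "G", "T"), ch[55])[1]
  mut <- paste(ch, collapse = "")
  expect_equal(nrow(scan_oligo("CCCTCTGCCAAACTCCAG", mut)), 0)
  h1 <- scan_oligo("CCCTCTGCCAAACTCCAG", mut, scan_policy(max_mismatches = 1))
  expect_true(50 %in% h1$start)
  expect_equal(h1$mismatches[h1$start == 50], 1)

  expect_equal(nrow(scan_oligo("CCCTCTGCCAAACTCCAG", "ACGT")), 0)
})

test_that("scanner agrees exactly with the expansion-set oracle", {
  set.seed(41)
  for (case in 1:600) {
    m <- sample(15:25, 1)
    oligo <- random_oligo(m)
    n <- sample(60:300, 1)
    subj <- random_subject(n)
    if (runif(1) < 0.5) {
      # embed a corrupted realization so hits actually occur
      k <- sample(0:3, 1)
      pos <- sample(n - m + 1, 1)
      subj <- paste0(substr(subj, 1, pos - 1), corrupted_site(oligo, k),
                     substr(subj, pos + m, n))
    }
    mm <- sample(0:2, 1); nn <- sample(0:2, 1)
    pol <- scan_policy(mm, nn, probe_orientation = "as_is")
    got <- scan_oligo(list(sequence = oligo, role = "fish_probe"), subj, pol)
    want <- oracle_scan(oligo, subj, mm, nn)
    expect_identical(got$start, want$start)
    expect_identical(got$mismatches, want$mismatches)
    expect_identical(got$n_positions, want$n_positions)
  }
})

test_that("hit sets are monotone in the mismatch budget and N allowance", {
  set.seed(51)
  for (case in 1:40) {
    oligo <- random_oligo(18)
    subj <- random_subject(250, p_n = 0.05)
    prev_mm <- NULL
    for (b in 0:2) {
      h <- scan_oligo(list(sequence = oligo, role = "fish_probe"), subj,
                      scan_policy(b, 1, "as_is"))
      if (!is.null(prev_mm)) expect_true(all(prev_mm %in% h$start))
      prev_mm <- h$start
    }
    prev_n <- NULL
    for (a in 0:2) {
      h <- scan_oligo(list(sequence = oligo, role = "fish_probe"), subj,
                      scan_policy(1, a, "as_is"))
      if (!is.null(prev_n)) expect_true(all(prev_n %in% h$start))
      prev_n <- h$start
    }
  }
})

test_that("in-silico PCR requires both primers, correct order, and length bounds", {
  ps <- fixture_primer_sets("515F-926R")[[1]]
  set.seed(61)
  flank <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                             collapse = "")
  fsite <- "GTGTCAGCAGCCGCGGTAA"            # realization of 515F
  rsite <- "AAACTCAAAGGAATTGACGG"           # realization of rc(926R)
  subj <- paste0(flank(100), fsite, flank(250), rsite, flank(60))
  amp <- simulate_pcr(ps, subj)
  expect_equal(nrow(amp), 1)
  expect_equal(amp$fwd_start, 100)
  expect_equal(amp$length, amp$rev_start + nchar(rsite) - amp$fwd_start)
  expect_equal(amp$length, 19 + 250 + 20)

  expect_equal(nrow(simulate_pcr(ps, paste0(flank(100), fsite, flank(100)))),
               0)
  swapped <- paste0(flank(100), rsite, flank(250), fsite, flank(60))
  expect_equal(nrow(simulate_pcr(ps, swapped)), 0)
  # within primer sites but outside the length bounds
  tight <- primer_set(ps$name, ps$forward, ps$reverse,
                      amplicon_length_bounds = c(50, 100))
  expect_equal(nrow(simulate_pcr(tight, subj)), 0)
})

test_that("pair amplifiability implies both single primers bind", {
  g <- fixture_synthetic(seed = 71)
  ps <- fixture_primer_sets("515F-926R")[[1]]
  for (i in seq_len(length(g$db))) {
    s <- g$db$seqs$sequence[i]
    if (nrow(simulate_pcr(ps, s)) > 0) {
      expect_true(probe_binds(ps$forward, s))
      expect_true(probe_binds(ps$reverse, s))
    }
  }
})

test_that("27F evaluability detects intact 5' ends and rejects truncated ones", {
  po <- parse_oligo_table(system.file("extdata", "primer_oligos.tsv",
                                      package = "oligocover"))
  f27 <- po[po$name == "27F", ]
  set.seed(81)
  tail <- paste(sample(c("A", "C", "G", "T"), 400, TRUE), collapse = "")
  intact <- paste0("AGAGTTTGATCCTGGCTCAG", tail)
  expect_true(is_27f_evaluable(intact, f27))
  # 5'-truncated: the primer region is gone
  expect_false(is_27f_evaluable(substr(intact, 120, nchar(intact)), f27))
  expect_false(is_27f_evaluable("ACGT", f27))
  # two mismatches in the primer region are still recognized (relaxed budget)
  mut <- intact
  substr(mut, 3, 3) <- "C"; substr(mut, 7, 7) <- "C"
  expect_true(is_27f_evaluable(mut, f27))
})

test_that("scanner matches Biostrings on concrete-base patterns", {
  set.seed(91)
  for (i in 1:20) {
    pat <- paste(sample(c("A", "C", "G", "T"), 16, TRUE), collapse = "")
    subj <- random_subject(400, p_n = 0, p_ambig = 0)
    got <- scan_oligo(list(sequence = pat, role = "primer_forward"), subj,
                      scan_policy(1, 0))$start
    ref <- Biostrings::matchPattern(pat, Biostrings::DNAString(subj),
                                    max.mismatch = 1)
    expect_identical(got, as.integer(BiocGenerics::start(ref)) - 1L)
  }
})
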