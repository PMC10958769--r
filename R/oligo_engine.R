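# Degenerate-oligo scanning engine: mismatch-bounded, IUPAC-aware window
# matching against reference sequences, probe-binding calls, in-silico PCR,
# and the 27F-evaluability (5'-truncation) rule.
#
# Matching semantics (per aligned position):
#   * match iff the subject symbol's expansion set is a subset of the oligo
#     symbol's expansion set (oligo-side degeneracy always expands);
#   * a literal subject 'N' is never a match; it is tallied separately and
#     consumed by the N allowance, not the mismatch budget;
#   * every other non-match consumes the mismatch budget.
# This mirrors a TestProbe-style "0 mismatches, 0 N's" evaluation at the
# default policy and replaces BLASTn-short for full-length ungapped hits.

#' Scanning policy
#'
#' @param max_mismatches Mismatch budget per window (default 0).
#' @param max_subject_n Allowance for subject `N` positions inside the window
#'   (default 0).
#' @param probe_orientation How a FISH probe is scanned against the deposited
#'   gene-sense sequence: `"revcomp_of_probe"` (default; probes hybridize to
#'   the rRNA, so their reverse complement matches the deposited strand),
#'   `"as_is"`, or `"both"`.
#' @return An object of class `scan_policy`.
#' @export
scan_policy <- function(max_mismatches = 0L, max_subject_n = 0L,
                        probe_orientation = c("revcomp_of_probe", "as_is",
                                              "both")) {
  probe_orientation <- match.arg(probe_orientation)
  stopifnot(max_mismatches >= 0, max_subject_n >= 0)
  structure(
    list(max_mismatches = as.integer(max_mismatches),
         max_subject_n = as.integer(max_subject_n),
         probe_orientation = probe_orientation),
    class = "scan_policy"
  )
}

as_oligo <- function(x, role = "fish_probe") {
  if (is.character(x) && length(x) == 1) {
    x <- list(name = x, sequence = x, role = role)
  }
  x <- as.list(x)
  stopifnot(!is.null(x$sequence))
  if (is.null(x$role)) x$role <- role
  if (is.null(x$name)) x$name <- x$sequence
  x$sequence <- normalize_sequence(x$sequence)
  stop_if_not_iupac(x$sequence, "oligo")
  x
}

# Oriented pattern(s) actually slid along the subject's sense strand.
scan_patterns <- function(oligo, policy) {
  s <- oligo$sequence
  if (identical(oligo$role, "fish_probe")) {
    switch(policy$probe_orientation,
      revcomp_of_probe = reverse_complement(s),
      as_is = s,
      both = unique(c(reverse_complement(s), s))
    )
  } else if (identical(oligo$role, "primer_reverse")) {
    reverse_complement(s)
  } else {
    s
  }
}

scan_pattern_windows <- function(pattern, subject, policy) {
  pat <- seq_to_mask(pattern)
  sub <- seq_to_mask(subject)
  is_n <- strsplit(subject, "")[[1]] == "N"
  hits <- .scan_windows_cpp(pat, sub, is_n,
                            policy$max_mismatches, policy$max_subject_n)
  as.data.frame(hits)
}

#' Mismatch and subject-N counts at one window
#'
#' Pure per-window evaluation of the matching semantics: useful for
#' inspecting a single candidate site.
#'
#' @param oligo IUPAC pattern as slid along the subject (no orientation
#'   handling here).
#' @param subject Subject sequence.
#' @param start 0-based window start; the window is
#'   `[start, start + nchar(oligo))`.
#' @return List with `mismatches` and `n_positions`.
#' @export
mismatches_at <- function(oligo, subject, start) {
  oligo <- normalize_sequence(oligo)
  subject <- normalize_sequence(subject)
  m <- nchar(oligo)
  stopifnot(start >= 0, start + m <= nchar(subject))
  win <- substr(subject, start + 1, start + m)
  pat <- seq_to_mask(oligo)
  sub <- seq_to_mask(win)
  ch <- strsplit(win, "")[[1]]
  is_n <- ch == "N"
  mm <- sum(!is_n & bitwAnd(sub, bitwAnd(bitwNot(pat), 15L)) != 0L)
  list(mismatches = mm, n_positions = sum(is_n))
}

#' Scan an oligo against a subject sequence
#'
#' Reports every window satisfying the policy's mismatch budget and subject-N
#' allowance, in ascending start order. FISH probes are oriented per
#' `policy$probe_orientation`; forward primers are scanned as-is and reverse
#' primers as their reverse complement, always along the deposited
#' (sense-strand) sequence.
#'
#' @param oligo An oligo-table row, a list with `sequence` and `role`, or a
#'   bare IUPAC string (treated as a FISH probe).
#' @param subject Subject sequence (string) or a single `ref_db` record id
#'   paired with `db`.
#' @param policy A [scan_policy()].
#' @return Data frame with 0-based `start`, `mismatches`, `n_positions`.
#' @export
scan_oligo <- function(oligo, subject, policy = scan_policy()) {
  oligo <- as_oligo(oligo)
  subject <- normalize_sequence(subject)
  if (nchar(oligo$sequence) > nchar(subject)) {
    return(data.frame(start = integer(0), mismatches = integer(0),
                      n_positions = integer(0)))
  }
  pats <- scan_patterns(oligo, policy)
  hits <- do.call(rbind, lapply(pats, scan_pattern_windows,
                                subject = subject, policy = policy))
  hits <- unique(hits)
  hits[order(hits$start), , drop = FALSE]
}

#' Does a probe bind a subject sequence?
#'
#' `TRUE` iff [scan_oligo()] reports at least one admissible window; a
#' sequence with multiple sites still counts once in every downstream
#' statistic.
#'
#' @inheritParams scan_oligo
#' @return Logical scalar.
#' @export
probe_binds <- function(oligo, subject, policy = scan_policy()) {
  nrow(scan_oligo(oligo, subject, policy)) > 0
}

# Binding calls for one oligo across a whole ref_db (internal workhorse).
binds_across_db <- function(oligo, db, policy) {
  oligo <- as_oligo(oligo)
  pats <- scan_patterns(oligo, policy)
  pat_masks <- lapply(pats, seq_to_mask)
  vapply(db$seqs$sequence, function(s) {
    sub <- seq_to_mask(s)
    is_n <- strsplit(s, "")[[1]] == "N"
    for (pm in pat_masks) {
      if (length(sub) >= length(pm) &&
          nrow(.scan_windows_cpp(pm, sub, is_n, policy$max_mismatches,
                                 policy$max_subject_n)) > 0) {
        return(TRUE)
      }
    }
    FALSE
  }, logical(1), USE.NAMES = FALSE)
}

#' In-silico PCR for a primer pair
#'
#' The forward primer must match the sense strand; the reverse primer's
#' reverse complement must match downstream, non-overlapping, with the
#' spanned interval (forward start to reverse-site end) inside the set's
#' amplicon length bounds. A subject is amplifiable iff at least one such
#' combination exists.
#'
#' @param pair A [primer_set()].
#' @param subject Subject sequence.
#' @param policy A [scan_policy()].
#' @return Data frame of amplicon hits with 0-based `fwd_start`,
#'   `rev_start`, and `length` (interval width on the sense strand).
#' @export
simulate_pcr <- function(pair, subject, policy = scan_policy()) {
  stopifnot(inherits(pair, "primer_set"))
  subject <- normalize_sequence(subject)
  empty <- data.frame(fwd_start = integer(0), rev_start = integer(0),
                      length = integer(0))
  fw <- scan_oligo(pair$forward, subject, policy)
  if (!nrow(fw)) return(empty)
  rv <- scan_oligo(pair$reverse, subject, policy)
  if (!nrow(rv)) return(empty)
  flen <- nchar(pair$forward$sequence)
  rlen <- nchar(pair$reverse$sequence)
  combos <- expand.grid(fwd_start = fw$start, rev_start = rv$start)
  combos$length <- combos$rev_start + rlen - combos$fwd_start
  keep <- combos$fwd_start + flen <= combos$rev_start &
    combos$length >= pair$min_len & combos$length <= pair$max_len
  out <- combos[keep, , drop = FALSE]
  rownames(out) <- NULL
  out[order(out$fwd_start, out$rev_start), , drop = FALSE]
}

#' Is a sequence evaluable for 27F-containing primer sets?
#'
#' Reference databases may contain 5'-truncated 16S sequences lacking the
#' 27F primer region; such records are removed from the coverage denominator
#' of 27F-containing sets rather than counted as amplification failures.
#' The primer region is detected with a relaxed budget
#' (`max_mismatches + extra_mismatches`) within the first `window` nt, so
#' the region is recognized even in sequences the strict scan would fail.
#'
#' @param subject Subject sequence.
#' @param fwd_27f The 27F-type forward primer (oligo row / list / string).
#' @param policy A [scan_policy()].
#' @param window Prefix length (nt) in which the primer region must start.
#' @param extra_mismatches Budget relaxation on top of the policy.
#' @return Logical scalar.
#' @export
is_27f_evaluable <- function(subject, fwd_27f, policy = scan_policy(),
                             window = 25L, extra_mismatches = 2L) {
  fwd_27f <- as_oligo(fwd_27f, role = "primer_forward")
  subject <- normalize_sequence(subject)
  if (nchar(subject) < nchar(fwd_27f$sequence)) return(FALSE)
  relaxed <- scan_policy(policy$max_mismatches + extra_mismatches,
                         policy$max_subject_n, policy$probe_orientation)
  hits <- scan_oligo(fwd_27f, subject, relaxed)
  any(hits$start < window)
}
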