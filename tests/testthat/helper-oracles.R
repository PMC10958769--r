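# Independent oracles, implemented from the definitions (expansion sets and
# textbook dynamic programming), deliberately separate from the package's
# bitmask/C++ routes.

oracle_expansion <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

# match table: rows = oligo symbol, cols = subject symbol; TRUE iff the
# subject symbol's expansion is a subset of the oligo symbol's expansion
oracle_match_table <- local({
  ch <- names(oracle_expansion)
  m <- matrix(FALSE, length(ch), length(ch), dimnames = list(ch, ch))
  for (o in ch) for (s in ch) {
    m[o, s] <- all(oracle_expansion[[s]] %in% oracle_expansion[[o]])
  }
  m
})

# position-by-position window matcher over all windows
oracle_scan <- function(pattern, subject, max_mm, max_n) {
  pc <- strsplit(pattern, "")[[1]]
  sc <- strsplit(subject, "")[[1]]
  m <- length(pc); n <- length(sc)
  if (n < m) {
    return(data.frame(start = integer(0), mismatches = integer(0),
                      n_positions = integer(0)))
  }
  win <- embed(seq_len(n), m)[, m:1, drop = FALSE]  # row i = window i indices
  subj_ch <- matrix(sc[win], nrow = nrow(win))
  is_n <- subj_ch == "N"
  match <- matrix(
    oracle_match_table[cbind(rep(pc, each = nrow(win)), as.vector(subj_ch))],
    nrow = nrow(win))
  mm <- rowSums(!match & !is_n)
  nn <- rowSums(is_n)
  keep <- mm <= max_mm & nn <= max_n
  data.frame(start = which(keep) - 1L, mismatches = as.integer(mm[keep]),
             n_positions = as.integer(nn[keep]))
}

# textbook global alignment (match +1, mismatch -1, gap -2; traceback ties
# diag > up > left), returning the identical-position count
oracle_nw <- function(a, b) {
  ac <- strsplit(a, "")[[1]]; bc <- strsplit(b, "")[[1]]
  la <- length(ac); lb <- length(bc)
  S <- matrix(0L, la + 1, lb + 1)
  D <- matrix(0L, la + 1, lb + 1)  # 0 diag, 1 up, 2 left
  S[1, ] <- (0:lb) * -2L; D[1, ] <- 2L
  S[, 1] <- (0:la) * -2L; D[, 1] <- 1L
  D[1, 1] <- 0L
  for (i in 2:(la + 1)) {
    for (j in 2:(lb + 1)) {
      d <- S[i - 1, j - 1] + if (ac[i - 1] == bc[j - 1]) 1L else -1L
      u <- S[i - 1, j] - 2L
      l <- S[i, j - 1] - 2L
      best <- max(d, u, l)
      S[i, j] <- best
      D[i, j] <- if (d == best) 0L else if (u == best) 1L else 2L
    }
  }
  i <- la + 1; j <- lb + 1; ident <- 0L
  while (i > 1 || j > 1) {
    if (i > 1 && j > 1 && D[i, j] == 0L) {
      if (ac[i - 1] == bc[j - 1]) ident <- ident + 1L
      i <- i - 1; j <- j - 1
    } else if (i > 1 && (D[i, j] == 1L || j == 1)) {
      i <- i - 1
    } else {
      j <- j - 1
    }
  }
  list(score = S[la + 1, lb + 1], identical = ident)
}

oracle_identity <- function(a, b) {
  oracle_nw(a, b)$identical / min(nchar(a), nchar(b))
}

# greedy clustering re-derived from the ordering rule over a precomputed
# identity matrix (identities from the package's aligner, logic independent)
oracle_greedy_cluster <- function(seqs, cutoff, identity_fun) {
  ord <- order(-nchar(seqs), names(seqs), method = "radix")
  ids <- names(seqs)[ord]
  assigned <- setNames(rep(NA_character_, length(ids)), ids)
  for (cid in ids) {
    if (!is.na(assigned[cid])) next
    assigned[cid] <- cid
    rest <- ids[is.na(assigned)]
    for (other in rest) {
      if (identity_fun(seqs[[cid]], seqs[[other]]) >= cutoff) {
        assigned[other] <- cid
      }
    }
  }
  assigned  # id -> centroid id
}

# random IUPAC pattern: mostly concrete bases with some ambiguity codes
random_oligo <- function(len, p_ambig = 0.2) {
  amb <- c("R", "Y", "S", "W", "K", "M", "B", "D", "H", "V", "N")
  ch <- ifelse(runif(len) < p_ambig,
               sample(amb, len, replace = TRUE),
               sample(c("A", "C", "G", "T"), len, replace = TRUE))
  paste(ch, collapse = "")
}

random_subject <- function(len, p_n = 0.02, p_ambig = 0.02) {
  ch <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
  r <- runif(len)
  ch[r < p_n] <- "N"
  amb <- c("R", "Y", "S", "W", "K", "M")
  idx <- r >= p_n & r < p_n + p_ambig
  ch[idx] <- sample(amb, sum(idx), replace = TRUE)
  paste(ch, collapse = "")
}

# realize a degenerate pattern and corrupt k positions
corrupted_site <- function(pattern, k) {
  ch <- strsplit(pattern, "")[[1]]
  ch <- vapply(ch, function(x) sample(oracle_expansion[[x]], 1), character(1))
  if (k > 0) {
    pos <- sample.int(length(ch), k)
    for (p in pos) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
  }
  paste(ch, collapse = "")
}
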