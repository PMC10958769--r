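# IUPAC nucleotide alphabet: bitmask encoding and sequence normalization.
# Masks: A=1, C=2, G=4, T=8; ambiguity codes are the bitwise union of the
# bases they denote. All matching semantics in the package reduce to subset
# tests on these masks.

IUPAC_EXPANSION <- c(
  A = "A", C = "C", G = "G", T = "T",
  R = "AG", Y = "CT", S = "CG", W = "AT", K = "GT", M = "AC",
  B = "CGT", D = "AGT", H = "ACT", V = "ACG", N = "ACGT"
)

IUPAC_MASK <- vapply(IUPAC_EXPANSION, function(ex) {
  base_bits <- c(A = 1L, C = 2L, G = 4L, T = 8L)
  sum(base_bits[strsplit(ex, "")[[1]]])
}, integer(1))

IUPAC_COMPLEMENT <- c(
  A = "T", C = "G", G = "C", T = "A",
  R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
  B = "V", D = "H", H = "D", V = "B", N = "N"
)

#' Normalize a nucleotide sequence
#'
#' Uppercases, converts RNA U to T, and strips alignment gap characters
#' (`-`, `.`) and whitespace, so that probes (DNA, 5'->3') can be compared
#' against deposited gene-sense sequences regardless of export artifacts.
#' Normalization is idempotent.
#'
#' @param x Character vector of sequences.
#' @return Character vector of normalized sequences.
#' @export
normalize_sequence <- function(x) {
  x <- toupper(x)
  x <- chartr("U", "T", x)
  gsub("[-.[:space:]]", "", x)
}

#' Validate sequences against the IUPAC nucleotide alphabet
#'
#' @param x Character vector of (normalized) sequences.
#' @return Logical vector: `TRUE` where every symbol is a valid IUPAC
#'   nucleotide code.
#' @export
is_iupac <- function(x) {
  !grepl(sprintf("[^%s]", paste(names(IUPAC_MASK), collapse = "")), x)
}

stop_if_not_iupac <- function(x, what = "sequence") {
  bad <- which(!is_iupac(x))
  if (length(bad)) {
    stop(sprintf("non-IUPAC symbol in %s (element %d: %s)",
                 what, bad[1], x[bad[1]]), call. = FALSE)
  }
  invisible(x)
}

#' Reverse complement of an IUPAC string
#'
#' Complements under the full IUPAC table (A<->T, C<->G, R<->Y, K<->M, S<->S,
#' W<->W, B<->V, D<->H, N<->N) and reverses. An involution: `rc(rc(s)) == s`.
#'
#' @param x Character vector of IUPAC sequences.
#' @return Character vector of reverse complements.
#' @export
reverse_complement <- function(x) {
  stop_if_not_iupac(x)
  from <- paste(names(IUPAC_COMPLEMENT), collapse = "")
  to <- paste(IUPAC_COMPLEMENT, collapse = "")
  comp <- chartr(from, to, x)
  vapply(strsplit(comp, ""), function(ch) {
    paste(rev(ch), collapse = "")
  }, character(1))
}

# Integer mask vector for one sequence (internal).
seq_to_mask <- function(s) {
  unname(IUPAC_MASK[strsplit(s, "")[[1]]])
}

# Random concrete realization of a degenerate sequence: each ambiguity code is
# replaced by a uniformly chosen member base. Uses the ambient RNG stream.
resolve_ambiguity <- function(s) {
  ch <- strsplit(s, "")[[1]]
  amb <- which(!ch %in% c("A", "C", "G", "T"))
  for (i in amb) {
    opts <- strsplit(IUPAC_EXPANSION[[ch[i]]], "")[[1]]
    ch[i] <- opts[sample.int(length(opts), 1)]
  }
  paste(ch, collapse = "")
}
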