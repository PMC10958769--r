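# Taxonomy refinement: pairwise identity under a fixed global alignment,
# CD-HIT-style greedy incremental clustering at an identity cut-off, and
# nearest-reference taxon assignment. The operational cut-offs follow the
# usual 16S conventions: 98.7% as a species boundary, 94.5% as a genus
# boundary; both are arguments, not constants.

#' Pairwise sequence identity
#'
#' Identity of the optimal global alignment under fixed scoring (match +1,
#' mismatch -1, linear gap -2; traceback ties resolved toward the
#' upper-left), with the CD-HIT denominator convention: identical aligned
#' positions divided by the length of the shorter sequence.
#'
#' @param a,b Nucleotide sequences (normalized internally).
#' @return Identity fraction in `[0, 1]`.
#' @export
pairwise_identity <- function(a, b) {
  a <- normalize_sequence(a)
  b <- normalize_sequence(b)
  stopifnot(nzchar(a), nzchar(b))
  st <- .nw_identity_cpp(a, b)
  st$identical / min(nchar(a), nchar(b))
}

#' Greedy incremental identity clustering
#'
#' CD-HIT-style: sequences are sorted by descending length (ties by id,
#' lexicographic); the longest unassigned sequence becomes a centroid and
#' every remaining unassigned sequence with identity >= `cutoff` to it joins
#' its cluster; repeat until all are assigned. Deterministic given the
#' ordering rule.
#'
#' @param seqs A `ref_db` or a named character vector of sequences.
#' @param cutoff Identity cut-off in (0, 1], e.g. 0.987 (species) or 0.945
#'   (genus).
#' @return Data frame with `seq_id`, `cluster_id`, `centroid_id`,
#'   `identity_to_centroid` (1 for centroids).
#' @export
greedy_cluster <- function(seqs, cutoff) {
  stopifnot(cutoff > 0, cutoff <= 1)
  if (inherits(seqs, "ref_db")) {
    seqs <- setNames(seqs$seqs$sequence, seqs$seqs$id)
  }
  stopifnot(!is.null(names(seqs)), !anyDuplicated(names(seqs)))
  ord <- order(-nchar(seqs), names(seqs), method = "radix")
  ids <- names(seqs)[ord]
  ss <- unname(seqs[ord])
  n <- length(ids)
  cluster <- integer(n)
  centroid <- character(n)
  ident <- numeric(n)
  next_cluster <- 0L
  for (i in seq_len(n)) {
    if (cluster[i] > 0L) next
    next_cluster <- next_cluster + 1L
    cluster[i] <- next_cluster
    centroid[i] <- ids[i]
    ident[i] <- 1
    if (i < n) {
      for (j in (i + 1L):n) {
        if (cluster[j] > 0L) next
        idj <- pairwise_identity(ss[i], ss[j])
        if (idj >= cutoff) {
          cluster[j] <- next_cluster
          centroid[j] <- ids[i]
          ident[j] <- idj
        }
      }
    }
  }
  data.frame(seq_id = ids, cluster_id = cluster, centroid_id = centroid,
             identity_to_centroid = ident, stringsAsFactors = FALSE)
}

#' Nearest-reference taxon assignment
#'
#' Assigns a query the taxon label of its highest-identity reference if that
#' identity reaches `min_identity`; ties break toward the lexicographically
#' smaller reference id. Below the threshold the query is `"unassigned"`
#' (monotone abstention: raising the threshold never changes a returned
#' label, it only flips labels to `"unassigned"`).
#'
#' @param query Query sequence (string).
#' @param references Named character vector of reference sequences (names =
#'   reference ids) -- or a `ref_db`.
#' @param labels Named character vector mapping reference id -> confirmed
#'   taxon label; for a `ref_db` default is the leaf taxonomy rank.
#' @param min_identity Assignment threshold (default 0.945, the genus
#'   boundary).
#' @return List with `label` (`"unassigned"` below threshold), `best_ref`,
#'   `identity`.
#' @export
assign_by_reference <- function(query, references, labels = NULL,
                                min_identity = 0.945) {
  if (inherits(references, "ref_db")) {
    if (is.null(labels)) {
      labels <- setNames(leaf_taxon(references, references$seqs$id),
                         references$seqs$id)
    }
    references <- setNames(references$seqs$sequence, references$seqs$id)
  }
  stopifnot(length(references) > 0, !is.null(names(references)),
            !is.null(labels))
  ids <- sort(names(references))
  idents <- vapply(ids, function(i) pairwise_identity(query, references[[i]]),
                   numeric(1))
  best <- ids[which.max(idents)]  # which.max takes the first = lexicographic
  list(
    label = if (idents[[best]] >= min_identity) unname(labels[[best]])
            else "unassigned",
    best_ref = best,
    identity = unname(idents[[best]])
  )
}

#' Build a refined target group by reference anchoring
#'
#' Runs [assign_by_reference()] for every database sequence and collects the
#' ids assigned to `taxon`, yielding an explicit-id target group that
#' replaces a raw taxonomy-predicate group in coverage runs.
#'
#' @param db A `ref_db` of query sequences.
#' @param references,labels,min_identity As in [assign_by_reference()].
#' @param taxon Confirmed taxon label to collect.
#' @return A `target_group` with explicit ids.
#' @export
refine_target_group <- function(db, references, labels = NULL,
                                taxon, min_identity = 0.945) {
  stopifnot(inherits(db, "ref_db"))
  assigned <- vapply(db$seqs$sequence, function(s) {
    assign_by_reference(s, references, labels, min_identity)$label
  }, character(1), USE.NAMES = FALSE)
  ids <- db$seqs$id[assigned == taxon]
  build_target_group(db, ids = ids, name = taxon)
}
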