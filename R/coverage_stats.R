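# Coverage and specificity statistics: per-probe and probe-mix coverage of a
# target taxon, non-target hits aggregated by taxon, Venn partitions of
# co-coverage, blind-spot (uncovered sequence) extraction, and 16S
# copy-number abundance correction.

#' Resolve a target group against a reference database
#'
#' Membership comes either from a taxonomy predicate -- a rank label matched
#' anywhere in the taxonomy path (so placeholder ranks such as `midas_g_94`
#' work) -- or from an explicit id list (e.g. a refined set from
#' [assign_by_reference()]), which overrides the predicate.
#'
#' @param db A `ref_db`.
#' @param predicate Rank label to match anywhere in the taxonomy path.
#' @param ids Explicit member ids (all must exist in `db`).
#' @param name Group name; defaults to the predicate.
#' @return An object of class `target_group` with `name` and `ids`. An empty
#'   group is returned with a warning; downstream coverage is then undefined
#'   (`NA`), never 0.
#' @export
build_target_group <- function(db, predicate = NULL, ids = NULL, name = NULL) {
  stopifnot(inherits(db, "ref_db"))
  if (is.null(predicate) && is.null(ids)) {
    stop("supply a taxonomy predicate or an explicit id list", call. = FALSE)
  }
  if (!is.null(ids)) {
    ids <- as.character(ids)
    missing <- setdiff(ids, db$seqs$id)
    if (length(missing)) {
      stop("explicit id not in database: ", missing[1], call. = FALSE)
    }
    if (is.null(name)) name <- "explicit"
  } else {
    hit <- vapply(db$taxonomy, function(tx) predicate %in% tx, logical(1))
    ids <- names(db$taxonomy)[hit]
    if (is.null(name)) name <- predicate
  }
  if (!length(ids)) {
    warning("empty target group '", name, "'", call. = FALSE)
  }
  message(sprintf("target group '%s': %d sequence(s)", name, length(ids)))
  structure(list(name = name, ids = ids), class = "target_group")
}

round_half_up <- function(x, digits = 1) {
  floor(x * 10^digits + 0.5) / 10^digits
}

#' Coverage percentage
#'
#' `100 * n_hit / n_total`, rounded half-up to one decimal so that printed
#' table arithmetic is bit-reproducible.
#'
#' @param n_hit Number of target sequences hit.
#' @param n_total Target group size.
#' @return Numeric; `NA` (undefined) when `n_total` is 0.
#' @export
coverage_percent <- function(n_hit, n_total) {
  stopifnot(all(n_hit >= 0), all(n_hit <= pmax(n_total, n_hit)))
  ifelse(n_total > 0, round_half_up(100 * n_hit / n_total, 1), NA_real_)
}

# Lowest-rank (leaf) taxon label of each sequence id.
leaf_taxon <- function(db, ids) {
  vapply(db$taxonomy[ids], function(tx) tx[length(tx)], character(1))
}

#' Binding matrix of oligos across a database
#'
#' @param oligos List of oligos (oligo-table rows, lists, or strings) or an
#'   oligo-table data frame.
#' @param db A `ref_db`.
#' @param policy A [scan_policy()].
#' @return Logical matrix, sequences x oligos, `TRUE` where the oligo binds.
#' @export
binding_matrix <- function(oligos, db, policy = scan_policy()) {
  stopifnot(inherits(db, "ref_db"))
  oligos <- oligo_list(oligos)
  pat_masks <- lapply(oligos, function(o) {
    lapply(scan_patterns(o, policy), seq_to_mask)
  })
  n <- length(db)
  out <- matrix(FALSE, nrow = n, ncol = length(oligos),
                dimnames = list(db$seqs$id,
                                vapply(oligos, `[[`, character(1), "name")))
  for (i in seq_len(n)) {
    s <- db$seqs$sequence[i]
    sub <- seq_to_mask(s)
    is_n <- strsplit(s, "")[[1]] == "N"
    for (k in seq_along(pat_masks)) {
      for (pm in pat_masks[[k]]) {
        if (length(sub) >= length(pm) &&
            nrow(.scan_windows_cpp(pm, sub, is_n, policy$max_mismatches,
                                   policy$max_subject_n)) > 0) {
          out[i, k] <- TRUE
          break
        }
      }
    }
  }
  out
}

oligo_list <- function(oligos) {
  if (is.data.frame(oligos)) {
    oligos <- lapply(seq_len(nrow(oligos)), function(i) oligos[i, ])
  } else if (!is.list(oligos) || !is.null(oligos$sequence)) {
    oligos <- list(oligos)
  }
  lapply(oligos, as_oligo)
}

coverage_report_from_calls <- function(name, db, group, bound) {
  in_group <- db$seqs$id %in% group$ids
  n_target <- sum(in_group)
  hit_ids <- db$seqs$id[bound]
  target_hit <- intersect(hit_ids, group$ids)
  nontarget_hit <- setdiff(hit_ids, group$ids)
  nt <- if (length(nontarget_hit)) {
    tab <- table(leaf_taxon(db, nontarget_hit))
    setNames(as.integer(tab), names(tab))
  } else {
    integer(0)
  }
  structure(
    list(
      oligo_or_mix_name = name,
      database_tag = db$seqs$source_db[1],
      group = group$name,
      n_target = n_target,
      n_target_hit = length(target_hit),
      coverage_pct = coverage_percent(length(target_hit), n_target),
      nontarget_hits = nt,
      uncovered_ids = sort(setdiff(group$ids, target_hit))
    ),
    class = "coverage_report"
  )
}

#' @export
print.coverage_report <- function(x, ...) {
  cat(sprintf("<coverage_report> %s on %s [%s]: %d/%d (%s%%), %d non-target\n",
              x$oligo_or_mix_name, x$group, x$database_tag, x$n_target_hit,
              x$n_target,
              ifelse(is.na(x$coverage_pct), "NA", format(x$coverage_pct)),
              sum(as.integer(x$nontarget_hits))))
  invisible(x)
}

#' Coverage and specificity of a single oligo
#'
#' Applies [probe_binds()] to every sequence in the database: coverage over
#' the target group, non-target hits aggregated by the out-group sequence's
#' lowest-rank taxon label, and the uncovered (blind-spot) ids.
#'
#' @param oligo An oligo (table row, list, or IUPAC string).
#' @param db A `ref_db`.
#' @param group A [build_target_group()] result.
#' @param policy A [scan_policy()].
#' @return A `coverage_report`.
#' @export
evaluate_oligo_coverage <- function(oligo, db, group,
                                    policy = scan_policy()) {
  oligo <- as_oligo(oligo)
  bound <- binding_matrix(list(oligo), db, policy)[, 1]
  coverage_report_from_calls(oligo$name, db, group, bound)
}

#' Union coverage of a probe mix
#'
#' A sequence is covered iff any probe in the mix binds it; non-target hits
#' are the union of the per-probe non-target hit sets.
#'
#' @param oligos Probes in the mix (oligo-table subset or list).
#' @param db A `ref_db`.
#' @param group A [build_target_group()] result.
#' @param policy A [scan_policy()].
#' @param mix_name Report label, e.g. `"PAOmix"`.
#' @return A `coverage_report`.
#' @export
evaluate_mix_coverage <- function(oligos, db, group, policy = scan_policy(),
                                  mix_name = NULL) {
  oligos <- oligo_list(oligos)
  if (is.null(mix_name)) {
    mix_name <- paste(vapply(oligos, `[[`, character(1), "name"),
                      collapse = "+")
  }
  bm <- binding_matrix(oligos, db, policy)
  coverage_report_from_calls(mix_name, db, group, rowSums(bm) > 0)
}

#' Venn partition of a target group by binding signature
#'
#' Partitions the group into the 2^k disjoint regions defined by which of
#' the k oligos bind each sequence (including the "none" region). Refuses
#' more than six oligos; use pairwise co-coverage instead at that scale.
#'
#' @param oligos 1--6 oligos.
#' @param db A `ref_db`.
#' @param group A [build_target_group()] result.
#' @param policy A [scan_policy()].
#' @return Data frame with `signature` (`+`-joined oligo names, `"none"` for
#'   the empty region) and `count`; counts sum to the group size.
#' @export
co_coverage_partition <- function(oligos, db, group,
                                  policy = scan_policy()) {
  oligos <- oligo_list(oligos)
  if (length(oligos) > 6) {
    stop("co_coverage_partition: more than 6 oligos; report a pairwise ",
         "co-coverage matrix instead", call. = FALSE)
  }
  bm <- binding_matrix(oligos, db, policy)
  bm <- bm[rownames(bm) %in% group$ids, , drop = FALSE]
  nms <- colnames(bm)
  sig <- apply(bm, 1, function(r) {
    if (!any(r)) "none" else paste(nms[r], collapse = "+")
  })
  # enumerate all 2^k regions so empty ones are reported as 0
  all_sigs <- c("none", unlist(lapply(seq_along(nms), function(k) {
    apply(utils::combn(nms, k), 2, paste, collapse = "+")
  })))
  counts <- table(factor(sig, levels = all_sigs))
  data.frame(signature = all_sigs, count = as.integer(counts),
             stringsAsFactors = FALSE)
}

#' Extract blind-spot sequences for a probe set
#'
#' Sequences in the target group hit by none of the given probes; the empty
#' probe set vacuously returns the whole group.
#'
#' @param oligos Probes evaluated for the taxon (possibly empty).
#' @param db A `ref_db`.
#' @param group A [build_target_group()] result.
#' @param policy A [scan_policy()].
#' @return Character vector of uncovered ids (sorted); export with
#'   [write_uncovered()].
#' @export
extract_uncovered <- function(oligos, db, group, policy = scan_policy()) {
  if (length(oligos) == 0 ||
      (is.data.frame(oligos) && nrow(oligos) == 0)) {
    return(sort(group$ids))
  }
  oligos <- oligo_list(oligos)
  bm <- binding_matrix(oligos, db, policy)
  covered <- rownames(bm)[rowSums(bm) > 0]
  sort(setdiff(group$ids, covered))
}

#' 16S copy-number correction of relative abundances
#'
#' Amplicon relative abundances over-represent taxa with many 16S rRNA gene
#' copies. Each abundance is divided by its taxon's copy number and the
#' result renormalized to the simplex:
#' `corrected_i = (a_i / c_i) / sum_j (a_j / c_j)`.
#'
#' @param abundances Named numeric vector of relative abundances summing
#'   to 1.
#' @param copy_numbers Named numeric vector of 16S copy numbers (>= 1);
#'   every taxon present in `abundances` must have one (no silent default).
#' @return Named numeric vector of corrected abundances summing to 1.
#' @export
copy_number_correct <- function(abundances, copy_numbers) {
  stopifnot(abs(sum(abundances) - 1) < 1e-9)
  missing <- setdiff(names(abundances), names(copy_numbers))
  if (length(missing)) {
    stop("missing 16S copy number for taxon: ", missing[1], call. = FALSE)
  }
  cn <- copy_numbers[names(abundances)]
  stopifnot(all(cn >= 1))
  w <- abundances / cn
  w / sum(w)
}
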