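# Synthetic reference databases with planted, machine-checkable truth.
#
# The generator emulates a taxonomically labelled 16S reference set: several
# taxa diverged from a common root, intra-taxon variation below the species
# boundary, probe-binding sites planted as the reverse complement of the
# probe (degenerate positions resolved at random so subject-side ambiguity
# is exercised), primer-pair amplicons planted within length bounds,
# optional subject-N positions, and optional 5'-truncated records. Every
# emitted database is self-checked by exhaustive re-scanning: the planted
# binder/amplifiable sets are exact, not probabilistic (sequences acquiring
# accidental sites are rejection-resampled).

random_chars <- function(n) sample(c("A", "C", "G", "T"), n, replace = TRUE)

mutate_chars <- function(ch, divergence) {
  L <- length(ch)
  k <- round(divergence * L)
  if (k == 0) return(ch)
  pos <- sample.int(L, k)
  bases <- c("A", "C", "G", "T")
  for (p in pos) {
    alt <- setdiff(bases, ch[p])
    ch[p] <- alt[sample.int(length(alt), 1)]
  }
  ch
}

#' Mutate a sequence away from a reference
#'
#' Substitutes exactly `round(divergence * length)` uniformly chosen
#' positions to a different base (no indels). Supports reference-assignment
#' tests where the realized divergence must be controlled.
#'
#' @param ref Reference sequence (string).
#' @param divergence Fraction in `[0, 1)`.
#' @param seed Optional integer; when given, the mutation is reproducible in
#'   isolation, otherwise the ambient RNG stream is used.
#' @return Mutated sequence (string).
#' @export
mutate_from_reference <- function(ref, divergence, seed = NULL) {
  stopifnot(divergence >= 0, divergence < 1)
  if (!is.null(seed)) set.seed(seed)
  ref <- normalize_sequence(ref)
  paste(mutate_chars(strsplit(ref, "")[[1]], divergence), collapse = "")
}

#' Synthetic database configuration
#'
#' Defaults describe a realistic 16S mock: 1200--1500 nt sequences,
#' inter-taxon divergence 10% (well past the genus boundary), intra-taxon
#' divergence up to 1.3% (within the 98.7% species boundary).
#'
#' @param taxa Named integer vector: taxon label -> number of sequences.
#' @param probes Oligo table subset (or `data.frame(name, sequence)`) of
#'   FISH probes available for planting.
#' @param probe_plant Data frame with columns `oligo`, `taxon`, and either
#'   `prob` (per-sequence planting probability) or `n` (exact count).
#' @param primer_sets Named list of [primer_set()] objects.
#' @param primer_plant Data frame with columns `set`, `taxon`, and `prob`
#'   or `n`.
#' @param len_range Sequence length range (nt); one length is drawn per
#'   taxon.
#' @param inter_divergence Divergence of each taxon ancestor from the root.
#' @param intra_divergence Maximum divergence of a member from its taxon
#'   ancestor.
#' @param frac_n Fraction of positions per sequence replaced by `N`
#'   (outside planted sites).
#' @param frac_truncated Fraction of sequences 5'-truncated by `trunc_len`
#'   nt (planted probe sites are placed downstream of the truncation point;
#'   5'-anchored forward-primer sites are destroyed, which is the point).
#' @param trunc_len Number of 5' nt removed from truncated records.
#' @param policy [scan_policy()] at which the planted truth is verified.
#' @param source_db Tag on the emitted database.
#' @return Config list for [generate_synthetic_db()].
#' @export
synthetic_db_config <- function(taxa,
                                probes = NULL, probe_plant = NULL,
                                primer_sets = NULL, primer_plant = NULL,
                                len_range = c(1200L, 1500L),
                                inter_divergence = 0.10,
                                intra_divergence = 0.013,
                                frac_n = 0, frac_truncated = 0,
                                trunc_len = 120L,
                                policy = scan_policy(),
                                source_db = "synthetic") {
  stopifnot(length(taxa) >= 1, !is.null(names(taxa)), all(taxa >= 1),
            frac_n >= 0, frac_n <= 1, frac_truncated >= 0,
            frac_truncated <= 1, len_range[1] <= len_range[2])
  list(taxa = taxa, probes = probes, probe_plant = probe_plant,
       primer_sets = primer_sets, primer_plant = primer_plant,
       len_range = as.integer(len_range),
       inter_divergence = inter_divergence,
       intra_divergence = intra_divergence,
       frac_n = frac_n, frac_truncated = frac_truncated,
       trunc_len = as.integer(trunc_len), policy = policy,
       source_db = source_db)
}

plant_ids <- function(plant, members_by_taxon, key) {
  out <- list()
  if (is.null(plant)) return(out)
  for (i in seq_len(nrow(plant))) {
    row <- plant[i, ]
    members <- members_by_taxon[[row$taxon]]
    if (is.null(members)) {
      stop("plant spec references unknown taxon: ", row$taxon, call. = FALSE)
    }
    chosen <- if (!is.null(row$n) && !is.na(row$n)) {
      stopifnot(row$n <= length(members))
      sample(members, row$n)
    } else {
      stopifnot(row$prob >= 0, row$prob <= 1)
      members[stats::runif(length(members)) < row$prob]
    }
    nm <- as.character(row[[key]])
    out[[nm]] <- c(out[[nm]], chosen)
  }
  lapply(out, sort)
}

# choose a free (non-overlapping) window of length w with start in
# [min_start, max_start]; returns start (1-based) or NA
pick_window <- function(occupied, L, w, min_start, max_start = L - w + 1L) {
  max_start <- min(max_start, L - w + 1L)
  for (try in 1:80) {
    if (min_start > max_start) return(NA_integer_)
    s <- sample(min_start:max_start, 1)
    iv <- c(s, s + w - 1)
    ok <- all(vapply(occupied, function(o) iv[2] < o[1] || iv[1] > o[2],
                     logical(1)))
    if (ok) return(s)
  }
  NA_integer_
}

#' Generate a synthetic reference database with planted truth
#'
#' @param config From [synthetic_db_config()].
#' @param seed Integer seed; the same seed yields byte-identical output.
#' @return List with `db` (a `ref_db`), and `truth`: `planted_binders`
#'   (oligo name -> ids), `planted_amplifiable` (primer-set name -> ids),
#'   `clade_membership` (id -> taxon), `truncated_ids`, `rng_seed`. The
#'   truth is verified by exhaustive re-scan before returning.
#' @export
generate_synthetic_db <- function(config, seed) {
  set.seed(as.integer(seed))
  taxa <- config$taxa
  probes <- if (!is.null(config$probes)) {
    setNames(normalize_sequence(config$probes$sequence),
             config$probes$name)
  } else character(0)
  if (length(probes)) stop_if_not_iupac(probes, "probe")
  psets <- config$primer_sets
  plant_min_start <- config$trunc_len + 61L

  # ids and membership
  ids <- unlist(lapply(names(taxa), function(tx) {
    sprintf("syn_%s_%03d", tx, seq_len(taxa[[tx]]))
  }))
  membership <- setNames(rep(names(taxa), taxa), ids)
  members_by_taxon <- split(ids, membership)[names(taxa)]

  # ancestors, rejected if they carry accidental oligo sites
  all_pat_masks <- c(
    lapply(probes, function(p) seq_to_mask(reverse_complement(p))),
    unlist(lapply(psets, function(ps) {
      list(seq_to_mask(normalize_sequence(ps$forward$sequence)),
           seq_to_mask(reverse_complement(ps$reverse$sequence)))
    }), recursive = FALSE)
  )
  has_accidental_site <- function(ch) {
    sub <- unname(IUPAC_MASK[ch])
    is_n <- ch == "N"
    for (pm in all_pat_masks) {
      if (length(sub) >= length(pm) &&
          nrow(.scan_windows_cpp(pm, sub, is_n,
                                 config$policy$max_mismatches,
                                 config$policy$max_subject_n)) > 0) {
        return(TRUE)
      }
    }
    FALSE
  }
  root <- random_chars(max(config$len_range))
  taxon_len <- setNames(
    sample(config$len_range[1]:config$len_range[2], length(taxa),
           replace = TRUE),
    names(taxa))
  ancestors <- lapply(names(taxa), function(tx) {
    for (try in 1:50) {
      anc <- mutate_chars(root[seq_len(taxon_len[[tx]])],
                          config$inter_divergence)
      if (!has_accidental_site(anc)) return(anc)
    }
    stop("could not draw an ancestor free of accidental oligo sites",
         call. = FALSE)
  })
  names(ancestors) <- names(taxa)

  # planting decisions (fixed before sequence realization)
  binders <- plant_ids(config$probe_plant, members_by_taxon, "oligo")
  amplifiable <- plant_ids(config$primer_plant, members_by_taxon, "set")
  trunc_n <- round(config$frac_truncated * length(ids))
  truncated <- sort(sample(ids, trunc_n))

  realize_sequence <- function(id) {
    tx <- membership[[id]]
    L <- taxon_len[[tx]]
    ch <- mutate_chars(ancestors[[tx]],
                       stats::runif(1, 0, config$intra_divergence))
    occupied <- list()
    for (pn in names(binders)) {
      if (!id %in% binders[[pn]]) next
      site <- strsplit(resolve_ambiguity(reverse_complement(probes[[pn]])),
                       "")[[1]]
      s <- pick_window(occupied, L, length(site), plant_min_start)
      if (is.na(s)) stop("no room to plant probe site", call. = FALSE)
      ch[s:(s + length(site) - 1)] <- site
      occupied <- c(occupied, list(c(s, s + length(site) - 1)))
    }
    for (sn in names(amplifiable)) {
      if (!id %in% amplifiable[[sn]]) next
      ps <- psets[[sn]]
      fseq <- strsplit(resolve_ambiguity(
        normalize_sequence(ps$forward$sequence)), "")[[1]]
      rsite <- strsplit(resolve_ambiguity(
        reverse_complement(ps$reverse$sequence)), "")[[1]]
      flen <- length(fseq); rlen <- length(rsite)
      amp_min0 <- max(ps$min_len, flen + rlen)
      placed <- FALSE
      for (outer in 1:40) {
        fs <- if (isTRUE(ps$anchored_5prime)) 1L else {
          # leave room downstream for the shortest admissible amplicon
          pick_window(occupied, L, flen, plant_min_start,
                      max_start = L - amp_min0 + 1L)
        }
        if (is.na(fs)) break
        amp_max <- min(ps$max_len, L - fs + 1L)
        if (amp_min0 > amp_max) next
        for (try in 1:40) {
          amp <- sample(amp_min0:amp_max, 1)
          rs <- fs + amp - rlen
          iv <- c(rs, rs + rlen - 1)
          ok <- rs >= fs + flen &&
            all(vapply(occupied, function(o) iv[2] < o[1] || iv[1] > o[2],
                       logical(1)))
          if (ok) { placed <- TRUE; break }
        }
        if (placed) break
      }
      if (!placed) stop("no room to plant primer pair", call. = FALSE)
      ch[fs:(fs + flen - 1)] <- fseq
      ch[rs:(rs + rlen - 1)] <- rsite
      occupied <- c(occupied, list(c(fs, fs + flen - 1)), list(iv))
    }
    if (config$frac_n > 0) {
      k <- round(config$frac_n * L)
      free <- setdiff(seq_len(L),
                      unlist(lapply(occupied, function(o) o[1]:o[2])))
      ch[sample(free, min(k, length(free)))] <- "N"
    }
    if (id %in% truncated) ch <- ch[-seq_len(config$trunc_len)]
    paste(ch, collapse = "")
  }

  seqs <- vapply(ids, realize_sequence, character(1))

  # truth, accounting for truncation of 5'-anchored primer sites
  truth_amplifiable <- amplifiable
  for (sn in names(truth_amplifiable)) {
    if (isTRUE(psets[[sn]]$anchored_5prime)) {
      truth_amplifiable[[sn]] <- setdiff(truth_amplifiable[[sn]], truncated)
    }
  }

  make_db <- function(seqs) {
    ref_db(ids, seqs,
           taxonomy = lapply(ids, function(i) c("Bacteria", membership[[i]])),
           source_db = config$source_db)
  }

  # self-check by exhaustive re-scan; resample offending sequences
  for (round in 1:20) {
    db <- make_db(seqs)
    bad <- character(0)
    for (pn in names(probes)) {
      ol <- list(name = pn, sequence = probes[[pn]], role = "fish_probe")
      hit <- db$seqs$id[binds_across_db(ol, db, config$policy)]
      bad <- c(bad, setdiff(hit, binders[[pn]]),
               setdiff(binders[[pn]], hit))
    }
    for (sn in names(psets)) {
      amp <- db$seqs$id[vapply(db$seqs$sequence, function(s) {
        nrow(simulate_pcr(psets[[sn]], s, config$policy)) > 0
      }, logical(1), USE.NAMES = FALSE)]
      want <- if (is.null(truth_amplifiable[[sn]])) character(0) else
        truth_amplifiable[[sn]]
      bad <- c(bad, setdiff(amp, want), setdiff(want, amp))
    }
    bad <- unique(bad)
    if (!length(bad)) break
    if (round == 20) {
      stop("self-check failed: could not realize planted truth exactly",
           call. = FALSE)
    }
    for (id in bad) seqs[[id]] <- realize_sequence(id)
  }

  list(
    db = db,
    truth = list(
      planted_binders = binders,
      planted_amplifiable = truth_amplifiable,
      clade_membership = as.list(membership),
      truncated_ids = truncated,
      rng_seed = as.integer(seed)
    )
  )
}

#' Write a synthetic truth object as JSON
#'
#' @param truth The `truth` component of [generate_synthetic_db()].
#' @param path Output JSON path.
#' @return Invisibly, `path`.
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
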