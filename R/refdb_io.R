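# Reference-database and oligo-table I/O.
#
# A ref_db holds normalized nucleotide sequences plus a ranked taxonomy path
# per record. FASTA headers are parsed under an explicitly declared dialect
# (never auto-detected silently):
#   silva: ">accession taxonomy;path;with;semicolons"
#   midas: ">FLASV_id<tab-or-space>d:...,p:...,g:...,s:..." (or ';'-separated)
#   plain: ">id|tax1;tax2;..."

#' Construct a reference database
#'
#' @param id Character vector of unique sequence identifiers.
#' @param sequence Character vector of nucleotide sequences (normalized with
#'   [normalize_sequence()] if needed).
#' @param taxonomy List of character vectors, each the ranked taxonomy path
#'   root -> leaf for the corresponding sequence.
#' @param source_db Single tag naming the source (e.g. `"silva-r138.1"`,
#'   `"synthetic"`).
#' @return An object of class `ref_db`.
#' @export
ref_db <- function(id, sequence, taxonomy, source_db = "unknown") {
  stopifnot(length(id) == length(sequence), length(id) == length(taxonomy))
  sequence <- normalize_sequence(sequence)
  if (anyDuplicated(id)) {
    stop("duplicate sequence id: ", id[duplicated(id)][1], call. = FALSE)
  }
  if (any(!nzchar(sequence))) {
    stop("empty sequence after normalization for id: ",
         id[!nzchar(sequence)][1], call. = FALSE)
  }
  stop_if_not_iupac(sequence, "reference sequence")
  tax_ok <- vapply(taxonomy, function(tx) {
    length(tx) > 0 && all(nzchar(tx))
  }, logical(1))
  if (any(!tax_ok)) {
    stop("empty taxonomy path or rank label for id: ", id[!tax_ok][1],
         call. = FALSE)
  }
  structure(
    list(
      seqs = data.frame(id = as.character(id), sequence = sequence,
                        source_db = source_db, stringsAsFactors = FALSE),
      taxonomy = setNames(taxonomy, id)
    ),
    class = "ref_db"
  )
}

#' @export
length.ref_db <- function(x) nrow(x$seqs)

#' @export
print.ref_db <- function(x, ...) {
  cat(sprintf("<ref_db> %d sequences from '%s'\n", length(x),
              x$seqs$source_db[1]))
  invisible(x)
}

#' Taxonomy index of a reference database
#'
#' @param db A `ref_db`.
#' @return Named list mapping each rank label occurring anywhere in a
#'   taxonomy path to the ids of the sequences carrying it.
#' @export
taxonomy_index <- function(db) {
  stopifnot(inherits(db, "ref_db"))
  labels <- rep(names(db$taxonomy), lengths(db$taxonomy))
  split(labels, unlist(db$taxonomy, use.names = FALSE))
}

parse_header <- function(headers, dialect) {
  switch(dialect,
    silva = {
      sp <- regexpr(" ", headers, fixed = TRUE)
      bad <- which(sp < 0)
      if (length(bad)) {
        stop(sprintf("malformed silva header at record %d: '%s'",
                     bad[1], headers[bad[1]]), call. = FALSE)
      }
      id <- substr(headers, 1, sp - 1)
      tax <- strsplit(substr(headers, sp + 1, nchar(headers)), ";", fixed = TRUE)
      list(id = id, taxonomy = tax)
    },
    midas = {
      sp <- regexpr("[ \t]", headers)
      bad <- which(sp < 0)
      if (length(bad)) {
        stop(sprintf("malformed midas header at record %d: '%s'",
                     bad[1], headers[bad[1]]), call. = FALSE)
      }
      id <- substr(headers, 1, sp - 1)
      raw <- substr(headers, sp + 1, nchar(headers))
      tax <- lapply(raw, function(tx) {
        parts <- strsplit(tx, "[,;]")[[1]]
        sub("^[a-z]:", "", trimws(parts))
      })
      list(id = id, taxonomy = tax)
    },
    plain = {
      sp <- regexpr("|", headers, fixed = TRUE)
      bad <- which(sp < 0)
      if (length(bad)) {
        stop(sprintf("malformed plain header at record %d: '%s'",
                     bad[1], headers[bad[1]]), call. = FALSE)
      }
      id <- substr(headers, 1, sp - 1)
      tax <- strsplit(substr(headers, sp + 1, nchar(headers)), ";", fixed = TRUE)
      list(id = id, taxonomy = tax)
    },
    stop("unknown header dialect: ", dialect, call. = FALSE)
  )
}

#' Read a taxonomically annotated reference FASTA
#'
#' @param path FASTA file path.
#' @param header_dialect One of `"silva"`, `"midas"`, `"plain"` (see package
#'   docs for the header grammars). The dialect is always explicit.
#' @param source_db Tag recorded on the returned database; defaults to the
#'   dialect name.
#' @return A `ref_db`. Records whose sequence is empty after normalization
#'   are dropped with a message; duplicate ids are a hard error.
#' @export
parse_reference_fasta <- function(path,
                                  header_dialect = c("plain", "silva", "midas"),
                                  source_db = NULL) {
  header_dialect <- match.arg(header_dialect)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (is.null(source_db)) source_db <- header_dialect
  xs <- Biostrings::readBStringSet(path)
  headers <- names(xs)
  seqs <- normalize_sequence(as.character(xs))
  hd <- parse_header(headers, header_dialect)
  empty <- !nzchar(seqs)
  if (any(empty)) {
    message(sprintf("parse_reference_fasta: dropped %d record(s) empty after normalization",
                    sum(empty)))
    seqs <- seqs[!empty]
    hd$id <- hd$id[!empty]
    hd$taxonomy <- hd$taxonomy[!empty]
  }
  message(sprintf("parse_reference_fasta: %d records read from '%s' (dialect %s)",
                  length(seqs), basename(path), header_dialect))
  ref_db(hd$id, seqs, hd$taxonomy, source_db = source_db)
}

#' Write a reference database as plain-dialect FASTA
#'
#' @param db A `ref_db`.
#' @param path Output path. Headers are `>id|tax1;tax2;...`.
#' @param width Line-wrap width for sequences.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(db, path, width = 70L) {
  stopifnot(inherits(db, "ref_db"))
  con <- file(path, open = "wb")  # binary: byte-identical across platforms
  on.exit(close(con))
  for (i in seq_len(length(db))) {
    id <- db$seqs$id[i]
    tax <- paste(db$taxonomy[[id]], collapse = ";")
    writeLines(sprintf(">%s|%s", id, tax), con, sep = "\n")
    s <- db$seqs$sequence[i]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))),
               con, sep = "\n")
  }
  invisible(path)
}

#' Read an oligo table
#'
#' Expects a TSV/CSV with columns `name`, `sequence`, `role`
#' (`fish_probe` / `primer_forward` / `primer_reverse`), `target_group`, and
#' optionally `formamide_pct` and `citation`. Sequences are uppercased and
#' U -> T converted; degenerate IUPAC codes are legal, anything else is a
#' hard error naming the row.
#'
#' @param path File path (`.tsv`/`.txt` tab-separated, `.csv` comma).
#' @return Data frame of validated oligos.
#' @export
parse_oligo_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  tb <- read.delim(path, sep = sep, stringsAsFactors = FALSE,
                   comment.char = "#")
  needed <- c("name", "sequence", "role", "target_group")
  miss <- setdiff(needed, names(tb))
  if (length(miss)) {
    stop("oligo table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  tb$sequence <- normalize_sequence(tb$sequence)
  bad <- which(!is_iupac(tb$sequence))
  if (length(bad)) {
    stop(sprintf("non-IUPAC oligo sequence in row %d (%s): %s",
                 bad[1], tb$name[bad[1]], tb$sequence[bad[1]]), call. = FALSE)
  }
  short <- which(nchar(tb$sequence) < 10)
  if (length(short)) {
    stop(sprintf("oligo shorter than 10 nt in row %d (%s)",
                 short[1], tb$name[short[1]]), call. = FALSE)
  }
  if (anyDuplicated(tb$name)) {
    stop("duplicate oligo name: ", tb$name[duplicated(tb$name)][1],
         call. = FALSE)
  }
  roles <- c("fish_probe", "primer_forward", "primer_reverse")
  if (any(!tb$role %in% roles)) {
    stop("invalid oligo role: ", tb$role[!tb$role %in% roles][1],
         call. = FALSE)
  }
  if (is.null(tb$formamide_pct)) tb$formamide_pct <- NA_real_
  if (is.null(tb$citation)) tb$citation <- NA_character_
  tb
}

#' Construct a primer set from two oligos
#'
#' @param name Set name, e.g. `"515F-926R"`.
#' @param forward,reverse Single rows of an oligo table (or lists with
#'   `name`, `sequence`, `role`) with roles `primer_forward` /
#'   `primer_reverse`.
#' @param region_label Targeted hypervariable region, e.g. `"V4-V5"`.
#' @param amplicon_length_bounds Inclusive `c(min, max)` on predicted
#'   amplicon length; the default suppresses spurious distant pairings.
#' @param anchored_5prime Logical: is the forward primer a 27F-type primer
#'   annealing at the 5' end of the gene (subject to the truncation omission
#'   rule)?
#' @return An object of class `primer_set`.
#' @export
primer_set <- function(name, forward, reverse, region_label = "",
                       amplicon_length_bounds = c(50L, 2500L),
                       anchored_5prime = FALSE) {
  forward <- as.list(forward)
  reverse <- as.list(reverse)
  stopifnot(identical(forward$role, "primer_forward"),
            identical(reverse$role, "primer_reverse"))
  b <- as.integer(amplicon_length_bounds)
  stopifnot(length(b) == 2, b[1] > 0, b[1] <= b[2])
  structure(
    list(name = name, forward = forward, reverse = reverse,
         region_label = region_label, min_len = b[1], max_len = b[2],
         anchored_5prime = isTRUE(anchored_5prime)),
    class = "primer_set"
  )
}

#' Build primer sets from an oligo table and a pairs table
#'
#' @param oligos Oligo table from [parse_oligo_table()].
#' @param pairs Data frame with columns `name`, `forward`, `reverse`
#'   (oligo names), optionally `region`, `min_len`, `max_len`,
#'   `anchored_5prime`.
#' @return Named list of `primer_set` objects.
#' @export
build_primer_sets <- function(oligos, pairs) {
  out <- lapply(seq_len(nrow(pairs)), function(i) {
    p <- pairs[i, ]
    fw <- oligos[oligos$name == p$forward, ]
    rv <- oligos[oligos$name == p$reverse, ]
    if (nrow(fw) != 1 || nrow(rv) != 1) {
      stop("primer pair '", p$name, "' references unknown oligo(s)",
           call. = FALSE)
    }
    bounds <- c(
      if (!is.null(p$min_len) && !is.na(p$min_len)) p$min_len else 50L,
      if (!is.null(p$max_len) && !is.na(p$max_len)) p$max_len else 2500L
    )
    primer_set(p$name, fw, rv,
               region_label = if (!is.null(p$region)) p$region else "",
               amplicon_length_bounds = bounds,
               anchored_5prime = !is.null(p$anchored_5prime) &&
                 isTRUE(as.logical(p$anchored_5prime)))
  })
  setNames(out, pairs$name)
}

#' Write coverage reports as a deterministic TSV
#'
#' Rows are ordered by oligo/mix name, then database tag, so identical report
#' collections serialize to identical bytes regardless of input order.
#' Coverage is printed with one decimal.
#'
#' @param reports A list of coverage reports (see
#'   [evaluate_oligo_coverage()]) or a data frame of report rows.
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_coverage_report <- function(reports, path) {
  df <- coverage_report_table(reports)
  df <- df[order(df$oligo_or_mix, df$database_tag), , drop = FALSE]
  df$coverage_pct <- ifelse(is.na(df$coverage_pct), "NA",
                            sprintf("%.1f", df$coverage_pct))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(names(df), collapse = "\t"), con)
  if (nrow(df)) {
    writeLines(do.call(paste, c(lapply(df, as.character), sep = "\t")), con)
  }
  invisible(path)
}

#' Flatten coverage reports to a data frame
#'
#' @param reports List of coverage reports, or an already-flat data frame.
#' @return Data frame with one row per report.
#' @export
coverage_report_table <- function(reports) {
  if (is.data.frame(reports)) return(reports)
  if (inherits(reports, "coverage_report")) reports <- list(reports)
  if (!length(reports)) {
    return(data.frame(
      oligo_or_mix = character(0), database_tag = character(0),
      target_group = character(0), n_target = integer(0),
      n_target_hit = integer(0), coverage_pct = numeric(0),
      n_nontarget_hit = integer(0),
      nontarget_taxa_breakdown = character(0),
      uncovered_ids_file = character(0), stringsAsFactors = FALSE))
  }
  rows <- lapply(reports, function(r) {
    breakdown <- if (length(r$nontarget_hits)) {
      o <- order(names(r$nontarget_hits))
      paste(sprintf("%s:%d", names(r$nontarget_hits)[o],
                    as.integer(r$nontarget_hits)[o]), collapse = ";")
    } else ""
    data.frame(
      oligo_or_mix = r$oligo_or_mix_name,
      database_tag = r$database_tag,
      target_group = r$group,
      n_target = r$n_target,
      n_target_hit = r$n_target_hit,
      coverage_pct = r$coverage_pct,
      n_nontarget_hit = sum(as.integer(r$nontarget_hits)),
      nontarget_taxa_breakdown = breakdown,
      uncovered_ids_file = if (is.null(r$uncovered_ids_file)) "" else
        r$uncovered_ids_file,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Export uncovered (blind-spot) sequences
#'
#' Writes the sequences of a target group hit by no evaluated oligo, with
#' taxonomy and source tag, mirroring a supplementary blind-spot table.
#'
#' @param db A `ref_db`.
#' @param ids Ids to export (e.g. `uncovered_ids` of a report).
#' @param path Output TSV path (columns `id`, `taxonomy`, `source_db`).
#' @return Invisibly, `path`.
#' @export
write_uncovered <- function(db, ids, path) {
  stopifnot(inherits(db, "ref_db"))
  ids <- sort(as.character(ids))
  tax <- vapply(ids, function(i) paste(db$taxonomy[[i]], collapse = ";"),
                character(1))
  src <- db$seqs$source_db[match(ids, db$seqs$id)]
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines("id\ttaxonomy\tsource_db", con)
  if (length(ids)) writeLines(paste(ids, tax, src, sep = "\t"), con)
  invisible(path)
}
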