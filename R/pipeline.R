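# End-to-end orchestration: config-driven probe and primer evaluation runs
# with structured logs, deterministic outputs, and a run manifest that makes
# every reported number traceable to database checksum + policy + version.

#' Read a run configuration from YAML
#'
#' @param path YAML file. See [run_probe_eval()] for the recognized fields.
#' @return Config list with a `scan_policy` attached.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  validate_run_config(cfg)
}

validate_run_config <- function(cfg) {
  stopifnot(!is.null(cfg$databases), !is.null(cfg$out_dir))
  tags <- vapply(cfg$databases, `[[`, character(1), "tag")
  if (anyDuplicated(tags)) {
    stop("duplicate database tag: ", tags[duplicated(tags)][1],
         call. = FALSE)
  }
  for (d in cfg$databases) {
    if (!file.exists(d$path)) stop("no such database: ", d$path,
                                   call. = FALSE)
  }
  pol <- cfg$policy
  cfg$policy <- scan_policy(
    max_mismatches = if (is.null(pol$max_mismatches)) 0L else
      pol$max_mismatches,
    max_subject_n = if (is.null(pol$max_subject_n)) 0L else
      pol$max_subject_n,
    probe_orientation = if (is.null(pol$probe_orientation))
      "revcomp_of_probe" else pol$probe_orientation
  )
  if (is.null(cfg$seed)) cfg$seed <- 1L
  cfg
}

load_config_dbs <- function(cfg) {
  lapply(cfg$databases, function(d) {
    db <- parse_reference_fasta(d$path, d$dialect, source_db = d$tag)
    attr(db, "mode_27f") <- if (is.null(d$mode_27f)) "apply_rule" else
      d$mode_27f
    attr(db, "path") <- d$path
    db
  })
}

resolve_groups <- function(cfg, db) {
  setNames(
    lapply(cfg$groups, function(g) {
      if (!is.null(g$ids_file)) {
        ids <- readLines(g$ids_file)
        build_target_group(db, ids = ids[nzchar(ids)], name = g$name)
      } else {
        build_target_group(db, predicate = g$predicate, name = g$name)
      }
    }),
    vapply(cfg$groups, `[[`, character(1), "name")
  )
}

write_manifest <- function(cfg, dbs, path) {
  cfg_file <- tempfile(fileext = ".yaml")
  on.exit(unlink(cfg_file))
  # hash the scientific configuration, not the output location
  keep <- cfg[setdiff(names(cfg), c("policy", "out_dir"))]
  keep$policy <- unclass(cfg$policy)
  yaml::write_yaml(keep[order(names(keep))], cfg_file)
  lines <- c(
    sprintf("oligocover_version\t%s",
            as.character(utils::packageVersion("oligocover"))),
    sprintf("config_md5\t%s", unname(tools::md5sum(cfg_file))),
    sprintf("seed\t%d", as.integer(cfg$seed)),
    vapply(dbs, function(db) {
      sprintf("database_md5\t%s\t%s", db$seqs$source_db[1],
              unname(tools::md5sum(attr(db, "path"))))
    }, character(1))
  )
  con <- file(path, open = "wb")
  writeLines(lines, con)
  close(con)
  invisible(path)
}

#' Run a full FISH-probe evaluation
#'
#' For every (probe, database, group) combination: a coverage report row;
#' for every declared mix a union report; Venn partition files per mix; a
#' blind-spot export per (group, database) over the probes declared for that
#' group; and a run manifest. All outputs are deterministic: identical
#' config and inputs produce byte-identical files.
#'
#' @param config Config list (or a [read_run_config()] result) with fields:
#'   `databases` (list of `path`/`dialect`/`tag`/`mode_27f`), `oligo_table`
#'   (path), `groups` (list of `name` + `predicate` or `ids_file`), `mixes`
#'   (named list: mix name -> probe names), `policy`, `out_dir`, `seed`.
#' @return Invisibly, the list of coverage reports.
#' @export
run_probe_eval <- function(config) {
  cfg <- validate_run_config(config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  oligos <- parse_oligo_table(cfg$oligo_table)
  probes <- oligos[oligos$role == "fish_probe", , drop = FALSE]
  dbs <- load_config_dbs(cfg)
  reports <- list()
  for (db in dbs) {
    tag <- db$seqs$source_db[1]
    groups <- resolve_groups(cfg, db)
    bm <- binding_matrix(probes, db, cfg$policy)
    for (g in groups) {
      if (!length(g$ids)) next
      for (k in seq_len(nrow(probes))) {
        rep <- coverage_report_from_calls(probes$name[k], db, g, bm[, k])
        reports[[length(reports) + 1]] <- rep
      }
      for (mx in names(cfg$mixes)) {
        members <- cfg$mixes[[mx]]
        cols <- match(members, colnames(bm))
        if (anyNA(cols)) {
          stop("mix '", mx, "' references unknown probe", call. = FALSE)
        }
        rep <- coverage_report_from_calls(
          mx, db, g, rowSums(bm[, cols, drop = FALSE]) > 0)
        reports[[length(reports) + 1]] <- rep
        if (length(cols) <= 6) {
          vp <- co_coverage_partition(probes[cols, ], db, g, cfg$policy)
          vf <- file.path(cfg$out_dir,
                          sprintf("venn_%s_%s_%s.tsv", mx, g$name, tag))
          con <- file(vf, open = "wb")
          writeLines(c("signature\tcount",
                       sprintf("%s\t%d", vp$signature, vp$count)), con)
          close(con)
        }
      }
      # blind spots over the probes declared for this group
      gp <- probes[probes$target_group == g$name, , drop = FALSE]
      if (!nrow(gp)) gp <- probes
      unc <- extract_uncovered(gp, db, g, cfg$policy)
      write_uncovered(db, unc,
                      file.path(cfg$out_dir,
                                sprintf("uncovered_%s_%s.tsv", g$name, tag)))
    }
  }
  write_coverage_report(reports,
                        file.path(cfg$out_dir, "probe_coverage.tsv"))
  write_manifest(cfg, dbs, file.path(cfg$out_dir, "manifest.tsv"))
  invisible(reports)
}

#' Run a primer-set (in-silico PCR) evaluation
#'
#' Per (primer set, database, group): amplifiable-sequence coverage at the
#' configured policy. 27F-containing sets are handled per the database's
#' `mode_27f`: `"apply_rule"` removes sequences lacking the 27F region from
#' the denominator (counts logged), `"skip_27f_sets"` marks the set
#' `not_evaluated` (the convention for databases whose deposited sequences
#' are uniformly primer-clipped), `"ignore"` applies no correction.
#'
#' @param config As in [run_probe_eval()], plus `primer_pairs`: path to a
#'   TSV with columns `name`, `forward`, `reverse`, optionally `region`,
#'   `min_len`, `max_len`, `anchored_5prime`.
#' @return Invisibly, a data frame of primer coverage rows.
#' @export
run_primer_eval <- function(config) {
  cfg <- validate_run_config(config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  oligos <- parse_oligo_table(cfg$oligo_table)
  pairs <- read.delim(cfg$primer_pairs, stringsAsFactors = FALSE,
                      comment.char = "#")
  psets <- build_primer_sets(oligos, pairs)
  dbs <- load_config_dbs(cfg)
  rows <- list()
  for (db in dbs) {
    tag <- db$seqs$source_db[1]
    mode <- attr(db, "mode_27f")
    groups <- resolve_groups(cfg, db)
    amp_by_set <- list()
    eval_27f <- list()
    for (ps in psets) {
      if (isTRUE(ps$anchored_5prime) && mode == "skip_27f_sets") next
      amp_by_set[[ps$name]] <- db$seqs$id[vapply(
        db$seqs$sequence,
        function(s) nrow(simulate_pcr(ps, s, cfg$policy)) > 0,
        logical(1), USE.NAMES = FALSE)]
      if (isTRUE(ps$anchored_5prime) && mode == "apply_rule") {
        eval_27f[[ps$name]] <- db$seqs$id[vapply(
          db$seqs$sequence,
          function(s) is_27f_evaluable(s, ps$forward, cfg$policy),
          logical(1), USE.NAMES = FALSE)]
      }
    }
    for (g in groups) {
      if (!length(g$ids)) next
      for (ps in psets) {
        if (isTRUE(ps$anchored_5prime) && mode == "skip_27f_sets") {
          rows[[length(rows) + 1]] <- data.frame(
            primer_set = ps$name, database_tag = tag, target_group = g$name,
            n_target = length(g$ids), n_omitted_27f = NA_integer_,
            n_amplifiable = NA_integer_, coverage_pct = NA_real_,
            status = "not_evaluated", stringsAsFactors = FALSE)
          next
        }
        denom_ids <- g$ids
        omitted <- 0L
        if (!is.null(eval_27f[[ps$name]])) {
          keep <- intersect(denom_ids, eval_27f[[ps$name]])
          omitted <- length(denom_ids) - length(keep)
          denom_ids <- keep
          message(sprintf(
            "primer set %s on %s/%s: omitted %d sequence(s) without 27F end",
            ps$name, tag, g$name, omitted))
        }
        n_amp <- length(intersect(denom_ids, amp_by_set[[ps$name]]))
        rows[[length(rows) + 1]] <- data.frame(
          primer_set = ps$name, database_tag = tag, target_group = g$name,
          n_target = length(denom_ids), n_omitted_27f = omitted,
          n_amplifiable = n_amp,
          coverage_pct = coverage_percent(n_amp, length(denom_ids)),
          status = "evaluated", stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$primer_set, out$database_tag, out$target_group), ,
             drop = FALSE]
  path <- file.path(cfg$out_dir, "primer_coverage.tsv")
  con <- file(path, open = "wb")
  writeLines(paste(names(out), collapse = "\t"), con)
  if (nrow(out)) {
    fmt <- out
    fmt$coverage_pct <- ifelse(is.na(out$coverage_pct), "NA",
                               sprintf("%.1f", out$coverage_pct))
    writeLines(do.call(paste, c(lapply(fmt, as.character), sep = "\t")), con)
  }
  close(con)
  write_manifest(cfg, dbs, file.path(cfg$out_dir, "manifest_primers.tsv"))
  invisible(out)
}
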