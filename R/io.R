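# File exchange formats: submission TSV (evidence_id <TAB> statement),
# JSON reports and TSV summaries.

#' Read a submission file
#'
#' Tab-separated, UTF-8, two columns per row: evidence identifier and one
#' raw BEL statement. Multiple rows per evidence are allowed; row order
#' is preserved. Blank lines and lines starting with `#` are skipped.
#' Statements are not parsed here -- syntactic validity is judged at
#' scoring (or by [bel_cli()]'s `validate` command).
#'
#' @param path Path to the TSV file.
#' @return Data frame with columns `evidence_id`, `text` and `line` (the
#'   source line number).
#' @export
bel_read_submission <- function(path) {
  if (!file.exists(path)) stop("submission file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  keep <- which(nzchar(trimws(lines)) & !startsWith(trimws(lines), "#"))
  if (length(keep) == 0L)
    return(data.frame(evidence_id = character(0), text = character(0),
                      line = integer(0), stringsAsFactors = FALSE))
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  bad <- which(lengths(fields) != 2L)
  if (length(bad) > 0L)
    stop(sprintf("line %d: expected 2 tab-separated columns, found %d",
                 keep[bad[1]], length(fields[[bad[1]]])))
  data.frame(
    evidence_id = vapply(fields, `[[`, character(1), 1L),
    text = vapply(fields, `[[`, character(1), 2L),
    line = keep,
    stringsAsFactors = FALSE
  )
}

#' Write a submission file
#'
#' @param x Data frame with columns `evidence_id` and `text`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
bel_write_submission <- function(x, path) {
  writeLines(paste(x$evidence_id, x$text, sep = "\t"), path, useBytes = TRUE)
  invisible(path)
}

#' Write ranked relevance judgments
#'
#' @param judgments A `bel_judgments` data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
bel_write_judgments <- function(judgments, path) {
  writeLines(paste(judgments$statement_id, judgments$rank,
                   judgments$evidence_id, judgments$label,
                   judgments$sentence_count, sep = "\t"),
             path, useBytes = TRUE)
  invisible(path)
}

.level_json <- function(m) {
  list(tp = m$tp, fp = m$fp, fn = m$fn,
       precision = bel_percent(m$precision),
       recall = bel_percent(m$recall),
       f = bel_percent(m$f))
}

#' Serialize a corpus report to JSON
#'
#' The report carries raw confusion counts plus percentages rounded
#' half-up to one decimal, overall and per evidence text, and the
#' matched/unmatched fragment lists of each evidence (the per-level true
#' positive pairs, false positive and false negative keys, and
#' placeholder predictions).
#'
#' @param report A `bel_corpus_report`.
#' @param path Output path for the JSON file.
#' @return `path`, invisibly.
#' @export
bel_write_report <- function(report, path) {
  per_ev <- lapply(report$evidences, function(ev) {
    list(
      evidence_id = ev$evidence_id,
      levels = lapply(ev$levels, function(m) {
        c(.level_json(m$metrics),
          list(pairs = m$pairs, fp = as.list(m$fp_keys),
               fn = as.list(m$fn_keys), placeholders = as.list(m$ph_keys)))
      }),
      rejected = ev$rejected
    )
  })
  out <- list(schema_version = "1.0",
              complex_members = "set semantics (order-insensitive)",
              overall = lapply(report$overall, .level_json),
              evidences = per_ev)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Write the TSV summary of a corpus report
#'
#' @param report A `bel_corpus_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
bel_write_summary <- function(report, path) {
  df <- bel_report_table(report)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Serialize ranking scores to JSON
#'
#' Mirrors the columns of the retrieval results table: TP, FP, precision
#' and the MAP values with their worst/random/best bounds, per criterion,
#' percentages rounded half-up to one decimal.
#'
#' @param scores A single `bel_ranking_scores` object or a list of them.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
bel_write_ranking <- function(scores, path) {
  if (inherits(scores, "bel_ranking_scores")) scores <- list(scores)
  out <- lapply(scores, function(s) list(
    criterion = s$criterion, tp = s$tp, fp = s$fp,
    precision = bel_percent(s$precision),
    map = bel_percent(s$map),
    worst = bel_percent(s$map_worst),
    random = bel_percent(s$map_random),
    best = bel_percent(s$map_best),
    n_statements = s$n_statements,
    n_shuffles = s$n_shuffles
  ))
  names(out) <- vapply(scores, `[[`, character(1), "criterion")
  jsonlite::write_json(list(schema_version = "1.0", criteria = out),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
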