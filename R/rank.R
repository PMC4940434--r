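# Ranked evidence-retrieval evaluation: average precision per statement,
# mean average precision (MAP) across statements, micro precision, and
# the worst / random / best reranking bounds.

.JUDGMENT_LABELS <- c("full", "relaxed", "context", "negative")

# nested relevance: an item judged "full" is relevant under all three
# criteria, "relaxed" under relaxed and context, "context" under context
.relevant_under <- function(labels, criterion) {
  criterion <- match.arg(criterion, c("full", "relaxed", "context"))
  keep <- switch(criterion,
                 full = "full",
                 relaxed = c("full", "relaxed"),
                 context = c("full", "relaxed", "context"))
  labels %in% keep
}

#' Average precision of a ranked relevance list
#'
#' Mean over the ranks r that hold a relevant item of the precision at r
#' (number of relevant items in the top r, divided by r). An empty list,
#' or a list without relevant items, scores 0.
#'
#' @param relevant Logical vector in rank order.
#' @return Average precision in \[0, 1\].
#' @examples
#' bel_average_precision(c(TRUE, FALSE, TRUE))  # (1/1 + 2/3) / 2
#' @export
bel_average_precision <- function(relevant) {
  relevant <- as.logical(relevant)
  if (length(relevant) == 0L || !any(relevant)) return(0)
  ranks <- which(relevant)
  mean(cumsum(relevant)[ranks] / ranks)
}

#' Read ranked relevance judgments from a tab-separated file
#'
#' Expected columns (no header): `statement_id`, `rank`, `evidence_id`,
#' `label` (one of `full`, `relaxed`, `context`, `negative`) and
#' `sentence_count`. Lines starting with `#` and blank lines are
#' skipped. Evidence texts longer than two sentences are discarded with
#' a warning (they would not have been judged); at most the 10
#' best-ranked evidences are kept per statement.
#'
#' @param path Path to the TSV file.
#' @return Data frame of class `bel_judgments`, ordered by statement and
#'   rank.
#' @export
bel_read_judgments <- function(path) {
  if (!file.exists(path)) stop("judgments file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  keep <- nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")
  lines <- lines[keep]
  if (length(lines) == 0L)
    stop("judgments file contains no data rows: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) != 5L)
  if (length(bad) > 0L)
    stop(sprintf("expected 5 tab-separated columns (row %d has %d)",
                 bad[1], length(fields[[bad[1]]])))
  df <- data.frame(
    statement_id = vapply(fields, `[[`, character(1), 1L),
    rank = as.integer(vapply(fields, `[[`, character(1), 2L)),
    evidence_id = vapply(fields, `[[`, character(1), 3L),
    label = vapply(fields, `[[`, character(1), 4L),
    sentence_count = as.integer(vapply(fields, `[[`, character(1), 5L)),
    stringsAsFactors = FALSE
  )
  if (anyNA(df$rank) || anyNA(df$sentence_count))
    stop("non-integer rank or sentence_count in judgments file")
  unknown <- setdiff(unique(df$label), .JUDGMENT_LABELS)
  if (length(unknown) > 0L)
    stop("unknown relevance label(s): ", paste(unknown, collapse = ", "))
  too_long <- df$sentence_count > 2L
  if (any(too_long)) {
    warning(sum(too_long),
            " evidence item(s) longer than two sentences discarded")
    df <- df[!too_long, , drop = FALSE]
  }
  df <- df[order(df$statement_id, df$rank), , drop = FALSE]
  trimmed <- unlist(lapply(split(seq_len(nrow(df)), df$statement_id),
                           function(ix) ix[seq_len(min(10L, length(ix)))]),
                    use.names = FALSE)
  if (length(trimmed) < nrow(df))
    warning("statements with more than 10 evidences truncated to the top 10")
  df <- df[sort(trimmed), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("bel_judgments", "data.frame")
  df
}

#' MAP with worst/random/best reranking bounds
#'
#' Computes, for one relevance criterion, the micro precision over all
#' judged evidences (total relevant / total judged), the mean average
#' precision over statements in the submitted rank order, and three
#' reference rankings of the same items: worst (every relevant item after
#' every irrelevant one), best (every relevant item first) and random
#' (MAP averaged over `n_shuffles` independent uniform reorderings of
#' each list; reproducible through `seed`, from which one substream per
#' statement is derived).
#'
#' @param judgments A `bel_judgments` data frame (see
#'   [bel_read_judgments()]).
#' @param criterion `"full"`, `"relaxed"` or `"context"`.
#' @param n_shuffles Number of random reorderings (default 2000).
#' @param seed Integer seed for the random bound.
#' @param zero_relevant How statements without any relevant evidence
#'   enter the MAP: `"include"` (AP = 0, the default) or `"exclude"`.
#' @return Object of class `bel_ranking_scores`: a list with `criterion`,
#'   `tp`, `fp`, `precision`, `map`, `map_worst`, `map_random`,
#'   `map_best`, `n_statements` and `n_shuffles`. `precision` and the
#'   MAP values are fractions in \[0, 1\].
#' @examples
#' j <- data.frame(statement_id = c("s1", "s1", "s2", "s2"),
#'                 rank = c(1, 2, 1, 2),
#'                 evidence_id = c("a", "b", "c", "d"),
#'                 label = c("full", "negative", "negative", "full"),
#'                 sentence_count = 1)
#' class(j) <- c("bel_judgments", "data.frame")
#' bel_map_with_bounds(j, "full", n_shuffles = 10, seed = 1)$map  # 0.75
#' @export
bel_map_with_bounds <- function(judgments, criterion = "full",
                                n_shuffles = 2000, seed = 1,
                                zero_relevant = c("include", "exclude")) {
  criterion <- match.arg(criterion, c("full", "relaxed", "context"))
  zero_relevant <- match.arg(zero_relevant)
  stopifnot(n_shuffles >= 1)
  lists <- lapply(split(judgments, judgments$statement_id), function(d) {
    d <- d[order(d$rank), , drop = FALSE]
    .relevant_under(d$label, criterion)
  })
  if (zero_relevant == "exclude")
    lists <- Filter(any, lists)
  if (length(lists) == 0L)
    stop("no statements to evaluate under criterion '", criterion, "'")
  ap <- vapply(lists, bel_average_precision, numeric(1))
  ap_worst <- vapply(lists, function(fl)
    bel_average_precision(sort(fl)), numeric(1))
  ap_best <- vapply(lists, function(fl)
    bel_average_precision(sort(fl, decreasing = TRUE)), numeric(1))
  # one deterministic substream per statement, derived from the global seed
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  substreams <- sample.int(.Machine$integer.max - 1L, length(lists))
  ap_random <- vapply(seq_along(lists), function(i) {
    fl <- lists[[i]]
    if (length(fl) <= 1L || all(fl) || !any(fl))
      return(bel_average_precision(fl))
    set.seed(substreams[i])
    mean(vapply(seq_len(n_shuffles), function(k)
      bel_average_precision(sample(fl)), numeric(1)))
  }, numeric(1))
  tp <- as.integer(sum(vapply(lists, sum, numeric(1))))
  n_items <- as.integer(sum(lengths(lists)))
  structure(list(
    criterion = criterion,
    tp = tp,
    fp = n_items - tp,
    precision = if (n_items > 0) tp / n_items else 0,
    map = mean(ap),
    map_worst = mean(ap_worst),
    map_random = mean(ap_random),
    map_best = mean(ap_best),
    n_statements = length(lists),
    n_shuffles = n_shuffles
  ), class = "bel_ranking_scores")
}

#' @export
print.bel_ranking_scores <- function(x, ...) {
  cat(sprintf(
    "<bel_ranking_scores> criterion=%s TP=%d FP=%d P=%.1f%% MAP=%.1f%% (worst %.1f%%, random %.1f%%, best %.1f%%)\n",
    x$criterion, x$tp, x$fp, bel_percent(x$precision), bel_percent(x$map),
    bel_percent(x$map_worst), bel_percent(x$map_random), bel_percent(x$map_best)))
  invisible(x)
}
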