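# Evidence-level scoring and micro-averaged aggregation.

#' Precision, recall and F-measure from confusion counts
#'
#' Conventions: precision is 0 when no positives were predicted, recall
#' is 0 when there are no gold items, F is 0 when precision + recall = 0.
#'
#' @param tp,fp,fn Non-negative counts.
#' @return List with `tp`, `fp`, `fn`, `precision`, `recall`, `f`
#'   (fractions in \[0, 1\]).
#' @export
bel_metrics <- function(tp, fp, fn) {
  stopifnot(tp >= 0, fp >= 0, fn >= 0)
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  list(tp = tp, fp = fp, fn = fn, precision = precision, recall = recall,
       f = bel_f_measure(precision, recall))
}

#' Harmonic mean of precision and recall
#'
#' @param precision,recall Same scale (both fractions or both percent).
#' @return `2 * precision * recall / (precision + recall)`, or 0 when the
#'   denominator is 0. The result is on the input scale.
#' @examples
#' bel_f_measure(9.2, 32.2)  # percent in, percent out
#' @export
bel_f_measure <- function(precision, recall) {
  if (precision + recall == 0) return(0)
  2 * precision * recall / (precision + recall)
}

#' Round-half-up percentage
#'
#' Converts a fraction to a percentage rounded half-up (the convention of
#' the evaluation reports, where e.g. 316/806 prints as 39.2%), avoiding
#' the round-half-even behaviour of [round()].
#'
#' @param x Fraction (or vector of fractions).
#' @param digits Decimal digits to keep (default 1).
#' @return Numeric percentage(s).
#' @examples
#' bel_percent(316 / 806)       # 39.2
#' bel_percent(62 / 105, 0)     # 59
#' @export
bel_percent <- function(x, digits = 1) {
  floor(x * 100 * 10^digits + 0.5) / 10^digits
}

#' Score the predictions for one evidence text
#'
#' Parses, simplifies and fragments the gold and predicted statements of
#' a single evidence text, then matches them at all six cascade levels.
#' Syntactically or semantically invalid statements are recorded as
#' rejected and excluded from scoring (their gold counterparts still
#' count toward false negatives, since all gold fragments remain).
#'
#' @param gold,pred Character vectors of raw BEL statement strings.
#' @param eq A [bel_equivalence()] applied during simplification.
#' @param evidence_id Identifier carried into the result.
#' @param levels Levels to score, a subset of [bel_levels()].
#' @return Object of class `bel_evidence_result`: a list with
#'   `evidence_id`, `levels` (per-level match results plus metrics from
#'   [bel_metrics()]), and `rejected` (data frame of rejected statements
#'   with columns `side`, `text`, `error`).
#' @export
bel_score_evidence <- function(gold, pred, eq = bel_equivalence(),
                               evidence_id = "", levels = bel_levels()) {
  levels <- match.arg(levels, bel_levels(), several.ok = TRUE)
  parse_all <- function(texts, side) {
    parsed <- list()
    rej_text <- character(0); rej_err <- character(0)
    for (tx in texts) {
      res <- tryCatch(bel_parse(tx), error = function(e) e)
      if (inherits(res, "error")) {
        rej_text <- c(rej_text, tx)
        rej_err <- c(rej_err, conditionMessage(res))
      } else {
        parsed[[length(parsed) + 1L]] <- bel_simplify(res, eq)
      }
    }
    list(parsed = parsed,
         rejected = if (length(rej_text))
           data.frame(side = side, text = rej_text, error = rej_err,
                      stringsAsFactors = FALSE)
         else NULL)
  }
  g <- parse_all(gold, "gold")
  p <- parse_all(pred, "pred")
  g_frag <- .pool_fragments(g$parsed)
  p_frag <- .pool_fragments(p$parsed)
  out <- stats::setNames(vector("list", length(levels)), levels)
  for (lv in levels) {
    m <- bel_match_level(g_frag[[lv]], p_frag[[lv]], lv)
    m$metrics <- bel_metrics(m$tp, m$fp, m$fn)
    out[[lv]] <- m
  }
  rejected <- do.call(rbind, c(list(g$rejected), list(p$rejected)))
  if (is.null(rejected))
    rejected <- data.frame(side = character(0), text = character(0),
                           error = character(0), stringsAsFactors = FALSE)
  structure(list(evidence_id = evidence_id, levels = out, rejected = rejected),
            class = "bel_evidence_result")
}

#' Aggregate evidence results into a micro-averaged corpus report
#'
#' Confusion counts are summed element-wise over evidence texts and
#' precision/recall/F recomputed from the sums (micro-averaging).
#'
#' @param results List of `bel_evidence_result` objects scored over the
#'   same levels.
#' @return Object of class `bel_corpus_report`: `evidences` (the input
#'   list) and `overall` (per-level [bel_metrics()]).
#' @export
bel_aggregate <- function(results) {
  stopifnot(length(results) >= 1L)
  levels <- names(results[[1]]$levels)
  overall <- stats::setNames(vector("list", length(levels)), levels)
  for (lv in levels) {
    tp <- sum(vapply(results, function(r) r$levels[[lv]]$tp, numeric(1)))
    fp <- sum(vapply(results, function(r) r$levels[[lv]]$fp, numeric(1)))
    fn <- sum(vapply(results, function(r) r$levels[[lv]]$fn, numeric(1)))
    overall[[lv]] <- bel_metrics(tp, fp, fn)
  }
  structure(list(evidences = results, overall = overall),
            class = "bel_corpus_report")
}

#' Score a full submission against a gold standard
#'
#' @param gold,pred Submissions as returned by [bel_read_submission()]
#'   (or any data frame with columns `evidence_id` and `text`). Evidence
#'   texts present in only one of the two sides are scored against an
#'   empty counterpart.
#' @param eq A [bel_equivalence()].
#' @param levels Levels to score.
#' @return A `bel_corpus_report` (see [bel_aggregate()]).
#' @examples
#' gold <- data.frame(evidence_id = "e1",
#'                    text = "act(p(MGI:Hras)) -> p(MGI:Mmp9)")
#' pred <- data.frame(evidence_id = "e1",
#'                    text = "p(MGI:Hras) -> p(MGI:Mmp9)")
#' rep <- bel_score_corpus(gold, pred)
#' rep$overall$relation$tp
#' @export
bel_score_corpus <- function(gold, pred, eq = bel_equivalence(),
                             levels = bel_levels()) {
  ids <- unique(c(gold$evidence_id, pred$evidence_id))
  results <- lapply(ids, function(id)
    bel_score_evidence(gold$text[gold$evidence_id == id],
                       pred$text[pred$evidence_id == id],
                       eq = eq, evidence_id = id, levels = levels))
  bel_aggregate(results)
}

#' @export
print.bel_corpus_report <- function(x, ...) {
  cat(sprintf("<bel_corpus_report> %d evidence text(s)\n", length(x$evidences)))
  df <- bel_report_table(x)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Summary table of a corpus report
#'
#' @param report A `bel_corpus_report`.
#' @return Data frame with one row per level: `level`, `tp`, `fp`, `fn`,
#'   `precision`, `recall`, `f` (percent, one decimal, rounded half-up).
#' @export
bel_report_table <- function(report) {
  lv <- names(report$overall)
  data.frame(
    level = lv,
    tp = vapply(report$overall, `[[`, numeric(1), "tp"),
    fp = vapply(report$overall, `[[`, numeric(1), "fp"),
    fn = vapply(report$overall, `[[`, numeric(1), "fn"),
    precision = vapply(report$overall, function(m) bel_percent(m$precision), numeric(1)),
    recall = vapply(report$overall, function(m) bel_percent(m$recall), numeric(1)),
    f = vapply(report$overall, function(m) bel_percent(m$f), numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
}
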