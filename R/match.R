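# Fragment matching. At every level, matching proceeds in deterministic
# phases over gold and predicted fragment multisets:
#   1. exact canonical-key matching (per-key count minima);
#   2. partial-credit matching, strongest predicate first, among
#      non-placeholder predictions:
#        function level:  complex() matches when it shares >= 1 member term;
#        relation level:  all three triple components must match, a
#                         complex() side matching on >= 1 shared member;
#        relation (secondary): all-three matches first, then any two of
#                         the three components; an association prediction
#                         whose subject and object are both correct also
#                         scores (the relation type was declared unknown);
#   3. placeholder accounting: remaining placeholder-bearing predictions
#      are wildcard-paired to remaining gold fragments for the report but
#      contribute neither a true nor a false positive -- the paired gold
#      still counts as a false negative;
#   4. remaining non-placeholder predictions are false positives,
#      remaining gold fragments false negatives.
# Ties are broken by input order (gold outer loop, first unmatched
# prediction); one prediction can earn at most one true positive.

.comp_match <- function(a, b) length(intersect(a, b)) > 0L

# number of matching components of two relation triples
.triple_score <- function(g, p) {
  sum(.comp_match(g$sub, p$sub),
      identical(g$rel, p$rel),
      .comp_match(g$obj, p$obj))
}

# wildcard predicate used only for pairing placeholder predictions in
# reports; PH components and the association relation match anything
.ph_wildcard_match <- function(g, p, level) {
  if (level %in% c("relation", "relation_secondary")) {
    sub_ok <- p$sub_ph || .comp_match(g$sub, p$sub)
    obj_ok <- p$obj_ph || .comp_match(g$obj, p$obj)
    rel_ok <- identical(p$rel, "--") || identical(g$rel, p$rel)
    return(sub_ok && obj_ok && rel_ok)
  }
  if (level == "function") {
    return(identical(g$name, p$name))
  }
  if (level == "term") {
    gfn <- sub("\\(.*$", "", g$key)
    pfn <- sub("\\(.*$", "", p$key)
    return(identical(gfn, pfn))
  }
  if (level == "full") {
    esc <- gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", p$key)
    pat <- gsub("PH:placeholder", ".+", esc, fixed = TRUE)
    pat <- gsub(" \\\\-\\\\- ", " (->|-\\\\||--) ", pat)
    return(grepl(paste0("^", pat, "$"), g$key))
  }
  FALSE
}

# ordered list of match passes for a level; each pass is a predicate over
# (gold fragment, pred fragment) plus an eligibility filter on predictions
.level_passes <- function(level) {
  exact <- list(pred = function(g, p) identical(g$key, p$key),
                eligible = function(p) TRUE, kind = "exact")
  passes <- list(exact)
  nonph <- function(p) !isTRUE(p$placeholder)
  if (level == "function") {
    passes <- c(passes, list(list(
      pred = function(g, p) identical(g$name, "complex") &&
        identical(p$name, "complex") && .comp_match(g$members, p$members),
      eligible = nonph, kind = "partial")))
  } else if (level == "relation") {
    passes <- c(passes, list(list(
      pred = function(g, p) .triple_score(g, p) == 3L,
      eligible = nonph, kind = "partial")))
  } else if (level == "relation_secondary") {
    passes <- c(passes, list(
      list(pred = function(g, p) .triple_score(g, p) == 3L,
           eligible = nonph, kind = "partial"),
      list(pred = function(g, p) .triple_score(g, p) >= 2L,
           eligible = nonph, kind = "partial"),
      # association used in place of the true relation: credit only when
      # both arguments are correct and neither is itself a placeholder
      list(pred = function(g, p) identical(p$rel, "--") &&
             !p$sub_ph && !p$obj_ph &&
             .comp_match(g$sub, p$sub) && .comp_match(g$obj, p$obj),
           eligible = function(p) identical(p$rel, "--"), kind = "association")))
  }
  passes
}

#' Match gold against predicted fragments at one cascade level
#'
#' Implements the deterministic phase-based matcher: exact canonical
#' matches first, then the level's partial-credit predicates
#' (strongest first), then placeholder accounting. Placeholder-bearing
#' predictions never count as false positives; the gold fragments they
#' stand in for remain false negatives, so placeholders affect recall
#' only.
#'
#' @param gold,pred Lists of fragments from [bel_fragments()], all at
#'   level `level`.
#' @param level One of [bel_levels()].
#' @return A list with counts `tp`, `fp`, `fn`, the pairing table
#'   `pairs` (columns `gold`, `pred`, `kind`), and the residual keys
#'   `fp_keys`, `fn_keys` and `ph_keys` (placeholder predictions that
#'   earned neither).
#' @export
bel_match_level <- function(gold, pred, level) {
  level <- match.arg(level, bel_levels())
  for (f in c(gold, pred))
    if (!identical(f$level, level))
      stop(sprintf("fragment at level '%s' passed to matcher for level '%s'",
                   f$level, level))
  ng <- length(gold); np <- length(pred)
  g_matched <- logical(ng); p_matched <- logical(np)
  pairs_g <- character(0); pairs_p <- character(0); pairs_k <- character(0)
  for (pass in .level_passes(level)) {
    if (ng == 0L || np == 0L) break
    for (gi in seq_len(ng)) {
      if (g_matched[gi]) next
      for (pi in seq_len(np)) {
        if (p_matched[pi] || !pass$eligible(pred[[pi]])) next
        if (pass$pred(gold[[gi]], pred[[pi]])) {
          g_matched[gi] <- TRUE; p_matched[pi] <- TRUE
          pairs_g <- c(pairs_g, gold[[gi]]$key)
          pairs_p <- c(pairs_p, pred[[pi]]$key)
          pairs_k <- c(pairs_k, pass$kind)
          break
        }
      }
    }
  }
  tp <- sum(g_matched)
  # placeholder accounting: wildcard-pair for the report only
  ph_idx <- which(!p_matched &
                    vapply(pred, function(p) isTRUE(p$placeholder), logical(1)))
  ph_keys <- character(0)
  ph_claimed <- logical(ng)
  for (pi in ph_idx) {
    ph_keys <- c(ph_keys, pred[[pi]]$key)
    for (gi in seq_len(ng)) {
      if (g_matched[gi] || ph_claimed[gi]) next
      if (.ph_wildcard_match(gold[[gi]], pred[[pi]], level)) {
        ph_claimed[gi] <- TRUE
        pairs_g <- c(pairs_g, gold[[gi]]$key)
        pairs_p <- c(pairs_p, pred[[pi]]$key)
        pairs_k <- c(pairs_k, "placeholder")
        break
      }
    }
  }
  fp_idx <- which(!p_matched &
                    !vapply(pred, function(p) isTRUE(p$placeholder), logical(1)))
  list(
    level = level,
    tp = tp,
    fp = length(fp_idx),
    fn = ng - tp,
    pairs = data.frame(gold = pairs_g, pred = pairs_p, kind = pairs_k,
                       stringsAsFactors = FALSE),
    fp_keys = vapply(pred[fp_idx], `[[`, character(1), "key"),
    fn_keys = vapply(gold[!g_matched], `[[`, character(1), "key"),
    ph_keys = ph_keys
  )
}
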