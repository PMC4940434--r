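# Reference matcher. An independent, matrix-based re-implementation of
# the matching rules used to cross-check the phase-based matcher in
# bel_match_level() and to derive the expected confusion counts attached
# to synthetically perturbed corpora. It enumerates every gold-prediction
# pair, evaluates the level's matching predicates directly into boolean
# matrices, and consumes them pass by pass in the documented tie-break
# order (gold input order, first unmatched prediction).

.oracle_triple_components <- function(g, p) {
  c(length(intersect(g$sub, p$sub)) > 0L,
    g$rel == p$rel,
    length(intersect(g$obj, p$obj)) > 0L)
}

# list of pairwise predicate matrices for a level, in match order
.oracle_matrices <- function(gold, pred, level) {
  ng <- length(gold); np <- length(pred)
  mat <- function(f) {
    m <- matrix(FALSE, ng, np)
    for (i in seq_len(ng)) for (j in seq_len(np)) m[i, j] <- f(gold[[i]], pred[[j]])
    m
  }
  ph <- vapply(pred, function(p) isTRUE(p$placeholder), logical(1))
  out <- list(mat(function(g, p) g$key == p$key))
  if (level == "function" && ng && np) {
    m <- mat(function(g, p)
      identical(g$name, "complex") && identical(p$name, "complex") &&
        length(intersect(g$members, p$members)) > 0L)
    m[, ph] <- FALSE
    out <- c(out, list(m))
  }
  if (level == "relation" && ng && np) {
    m <- mat(function(g, p) all(.oracle_triple_components(g, p)))
    m[, ph] <- FALSE
    out <- c(out, list(m))
  }
  if (level == "relation_secondary" && ng && np) {
    m3 <- mat(function(g, p) all(.oracle_triple_components(g, p)))
    m2 <- mat(function(g, p) sum(.oracle_triple_components(g, p)) >= 2L)
    m3[, ph] <- FALSE
    m2[, ph] <- FALSE
    massoc <- mat(function(g, p)
      p$rel == "--" && !p$sub_ph && !p$obj_ph &&
        length(intersect(g$sub, p$sub)) > 0L &&
        length(intersect(g$obj, p$obj)) > 0L)
    massoc[, vapply(pred, function(p) p$rel != "--", logical(1))] <- FALSE
    out <- c(out, list(m3, m2, massoc))
  }
  out
}

#' Reference confusion counts by exhaustive pairwise matching
#'
#' Independent cross-check for [bel_match_level()]: evaluates the matching
#' predicate for every gold-prediction fragment pair into boolean
#' matrices and consumes them greedily in the documented order. Counts
#' agree with the phase-based matcher by construction of the shared
#' matching rules; the two implementations share no matching code.
#'
#' @inheritParams bel_match_level
#' @return A list with counts `tp`, `fp`, `fn`.
#' @export
bel_oracle_match <- function(gold, pred, level) {
  level <- match.arg(level, bel_levels())
  ng <- length(gold); np <- length(pred)
  ph <- vapply(pred, function(p) isTRUE(p$placeholder), logical(1))
  if (ng == 0L || np == 0L) {
    return(list(tp = 0L, fp = sum(!ph), fn = ng))
  }
  g_free <- rep(TRUE, ng); p_free <- rep(TRUE, np)
  tp <- 0L
  for (m in .oracle_matrices(gold, pred, level)) {
    for (i in seq_len(ng)) {
      if (!g_free[i]) next
      js <- which(m[i, ] & p_free)
      if (length(js) > 0L) {
        g_free[i] <- FALSE
        p_free[js[1]] <- FALSE
        tp <- tp + 1L
      }
    }
  }
  list(tp = tp, fp = sum(p_free & !ph), fn = sum(g_free))
}
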