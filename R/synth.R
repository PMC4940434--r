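# Grammar-driven synthetic corpus generation. Statements are drawn from
# the restricted BEL grammar with the class proportions of the reference
# training corpus (87% of terms are proteins, 69% of functions are
# activities, 73% of relations express an increase); predictions are
# derived from the gold corpus by controlled perturbation operators, and
# every perturbed pair carries expected per-level confusion counts
# computed with the reference matcher, so end-to-end scoring can be
# verified against known ground truth.

# small fixed symbol pools per namespace; deliberately including symbols
# that also appear in the printed grammar examples so generated corpora
# stay human-checkable
.BEL_POOLS <- list(
  HGNC = c("MAPK14", "TP53", "TIMP1", "MMP9", "VEGFA", "KDR", "BCL2A1",
           "FAS", "RB1", "SCOC", "CD36", "IL6", "TNF", "EGFR", "AKT1"),
  MGI = c("Mapk14", "Cav1", "Bmp4", "Acta2", "Itga8", "Itgb1", "Lyve1",
          "Stk16", "Hras", "Mmp9", "Cckbr", "Gast", "Prkd1", "Trp53"),
  EGID = c("1432", "7157", "4318", "7422", "3791", "597", "355", "5925"),
  GOBP = c("cell proliferation", "cell adhesion", "apoptotic process",
           "angiogenesis", "inflammatory response", "cell migration"),
  MESHD = c("Hyperoxia", "Inflammation", "Neoplasms", "Fibrosis",
            "Hypertension"),
  CHEBI = c("nitric oxide", "lipopolysaccharide", "brefeldin A",
            "hyaluronic acid", "calcium", "reactive oxygen species")
)

#' Configuration for the synthetic corpus generator
#'
#' Defaults reflect the class distribution of the reference training
#' corpus: 87% of terms are proteins, 69% of functions are activities
#' and 73% of relations express an increase.
#'
#' @param n_evidences Number of evidence texts.
#' @param statements_min,statements_max Statements per evidence are drawn
#'   uniformly from this range.
#' @param p_protein Probability that a term is a protein `p()` term.
#' @param p_activity Probability that a function wrapper is an activity
#'   (`act`/`kin`/`cat`/`tscript`).
#' @param p_increase Probability that the relation expresses an increase.
#' @param p_association Probability of an `association` relation
#'   (default 0; gold corpora normally state a direction).
#' @param p_direct Probability that an increase/decrease is written in
#'   its `directly*` form.
#' @param p_function_subject,p_function_object Probability that the
#'   subject/object carries a function wrapper.
#' @return List of class `bel_synth_config`.
#' @export
bel_synth_config <- function(n_evidences = 50,
                             statements_min = 1, statements_max = 3,
                             p_protein = 0.87,
                             p_activity = 0.69,
                             p_increase = 0.73,
                             p_association = 0,
                             p_direct = 0.2,
                             p_function_subject = 0.45,
                             p_function_object = 0.25) {
  cfg <- list(n_evidences = n_evidences,
              statements_min = statements_min,
              statements_max = statements_max,
              p_protein = p_protein, p_activity = p_activity,
              p_increase = p_increase, p_association = p_association,
              p_direct = p_direct,
              p_function_subject = p_function_subject,
              p_function_object = p_function_object)
  probs <- unlist(cfg[startsWith(names(cfg), "p_")])
  stopifnot(all(probs >= 0 & probs <= 1),
            cfg$p_increase + cfg$p_association <= 1,
            statements_min >= 1, statements_max >= statements_min)
  structure(cfg, class = "bel_synth_config")
}

.draw <- function(items, weights) {
  items[sample.int(length(items), 1L, prob = weights)]
}

.sample_entity <- function(ns) {
  bel_entity(ns, sample(.BEL_POOLS[[ns]], 1L))
}

# one plain term; protein share per config, the non-protein remainder
# split over processes, pathologies, chemicals, genes and RNA
.sample_term <- function(config) {
  rest <- c(bp = 0.30, a = 0.30, path = 0.15, g = 0.12, r = 0.08, m = 0.05)
  fns <- c("p", names(rest))
  w <- c(config$p_protein, (1 - config$p_protein) * rest / sum(rest))
  fn <- .draw(fns, w)
  ns <- switch(fn,
               bp = "GOBP", path = "MESHD", a = "CHEBI",
               m = .draw(c("HGNC", "MGI"), c(0.6, 0.4)),
               .draw(c("HGNC", "MGI", "EGID"), c(0.5, 0.35, 0.15)))
  bel_term(fn, .sample_entity(ns))
}

.sample_protein_term <- function(config) {
  ns <- .draw(c("HGNC", "MGI", "EGID"), c(0.5, 0.35, 0.15))
  bel_term("p", .sample_entity(ns))
}

# wrap a term in a function; activity share per config, the remainder
# split over complex, deg, tloc and pmod
.sample_wrapped <- function(term, config) {
  rest <- c(complex = 0.12, deg = 0.07, tloc = 0.06, pmod = 0.06)
  w <- c(config$p_activity, (1 - config$p_activity) * rest / sum(rest))
  kind <- .draw(c("activity", names(rest)), w)
  if (kind == "pmod" && !identical(term$fn, "p")) kind <- "activity"
  switch(kind,
    activity = bel_fterm(.draw(c("act", "kin", "cat", "tscript"),
                               c(0.7, 0.1, 0.1, 0.1)), list(term)),
    complex = {
      other <- .sample_protein_term(config)
      bel_fterm("complex", list(term, other))
    },
    deg = bel_fterm("deg", list(term)),
    tloc = {
      extra <- if (stats::runif(1) < 0.3) "GOCC:endosome" else character(0)
      bel_fterm("tloc", list(term), extra)
    },
    pmod = {
      args <- if (stats::runif(1) < 0.3) c("P", "S", "15") else "P"
      bel_fterm("none", list(bel_term(term$fn, term$entity,
                                      list(list(kind = "pmod", args = args)))))
    })
}

.sample_side <- function(config, p_function) {
  term <- .sample_term(config)
  if (stats::runif(1) < p_function) .sample_wrapped(term, config)
  else bel_fterm("none", list(term))
}

#' Draw one random BEL statement
#'
#' Uses the current RNG state; seed at the corpus level for
#' reproducibility. Generated statements always pass [bel_validate()].
#'
#' @param config A [bel_synth_config()].
#' @return A [bel_statement()].
#' @export
bel_sample_statement <- function(config = bel_synth_config()) {
  u <- stats::runif(1)
  rel <- if (u < config$p_increase) {
    if (stats::runif(1) < config$p_direct) "=>" else "->"
  } else if (u < config$p_increase + config$p_association) {
    "--"
  } else {
    if (stats::runif(1) < config$p_direct) "=|" else "-|"
  }
  bel_statement(.sample_side(config, config$p_function_subject), rel,
                .sample_side(config, config$p_function_object))
}

#' Generate a synthetic gold corpus
#'
#' @param config A [bel_synth_config()].
#' @param seed Integer seed.
#' @return Data frame with columns `evidence_id` and `text` (one rendered
#'   statement per row), the submission exchange format.
#' @examples
#' head(bel_sample_corpus(bel_synth_config(n_evidences = 3), seed = 7))
#' @export
bel_sample_corpus <- function(config = bel_synth_config(), seed = 1) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  ids <- character(0); texts <- character(0)
  for (i in seq_len(config$n_evidences)) {
    span <- seq(config$statements_min, config$statements_max)
    n <- if (length(span) == 1L) span else sample(span, 1L)
    for (k in seq_len(n)) {
      ids <- c(ids, sprintf("ev%04d", i))
      texts <- c(texts, bel_render(bel_sample_statement(config)))
    }
  }
  data.frame(evidence_id = ids, text = texts, stringsAsFactors = FALSE)
}

# ---- perturbation operators ----------------------------------------------

.BEL_PERTURB_OPS <- c("swap_entity", "flip_relation", "drop_function",
                      "change_function", "insert_placeholder",
                      "drop_statement", "add_spurious")

# rebuild a statement with term number k (in traversal order) replaced by
# f(term); counter shared across subject/object
.modify_term <- function(st, k, f) {
  counter <- new.env(parent = emptyenv()); counter$i <- 0L
  mod_ft <- function(ft) {
    terms <- lapply(ft$terms, function(t) {
      counter$i <- counter$i + 1L
      if (counter$i == k) f(t) else t
    })
    bel_fterm(ft$wrapper, terms, ft$extra)
  }
  obj <- if (inherits(st$object, "bel_statement"))
    bel_statement(mod_ft(st$object$subject), st$object$relation,
                  mod_ft(st$object$object))
  else mod_ft(st$object)
  bel_statement(mod_ft(st$subject), st$relation, obj)
}

.op_swap_entity <- function(st, config) {
  terms <- .collect_terms(st)
  k <- sample.int(length(terms), 1L)
  old <- terms[[k]]
  .modify_term(st, k, function(t) {
    pool <- setdiff(.BEL_POOLS[[t$entity$ns]], t$entity$value)
    if (length(pool) == 0L) return(t)
    bel_term(t$fn, bel_entity(t$entity$ns, sample(pool, 1L)), t$mods)
  })
}

.op_flip_relation <- function(st, config) {
  flipped <- switch(st$relation,
                    "->" = "-|", "-|" = "->", "=>" = "=|", "=|" = "=>",
                    st$relation)
  bel_statement(st$subject, flipped, st$object)
}

.op_insert_placeholder <- function(st, config) {
  terms <- .collect_terms(st)
  k <- sample.int(length(terms), 1L)
  .modify_term(st, k, function(t)
    bel_term(t$fn, bel_entity("PH", "placeholder"), t$mods))
}

.strip_one_side <- function(ft) {
  t <- ft$terms[[1]]
  bel_fterm("none", list(bel_term(t$fn, t$entity, list())))
}

.op_drop_function <- function(st, config) {
  sides <- list(st$subject,
                if (inherits(st$object, "bel_statement")) NULL else st$object)
  has_fn <- function(ft) !is.null(ft) &&
    (!identical(ft$wrapper, "none") || any(lengths(lapply(ft$terms, `[[`, "mods")) > 0))
  target <- which(vapply(sides, has_fn, logical(1)))
  if (length(target) == 0L) return(st)
  pick <- target[sample.int(length(target), 1L)]
  if (pick == 1L)
    bel_statement(.strip_one_side(st$subject), st$relation, st$object)
  else
    bel_statement(st$subject, st$relation, .strip_one_side(st$object))
}

.op_change_function <- function(st, config) {
  change <- function(ft) {
    if (identical(ft$wrapper, "none")) return(ft)
    alt <- setdiff(c("act", "deg", "tloc"),
                   if (ft$wrapper %in% .BEL_ACT_FAMILY) "act" else ft$wrapper)
    bel_fterm(sample(alt, 1L), ft$terms[1], character(0))
  }
  if (!identical(st$subject$wrapper, "none"))
    bel_statement(change(st$subject), st$relation, st$object)
  else if (!inherits(st$object, "bel_statement") &&
           !identical(st$object$wrapper, "none"))
    bel_statement(st$subject, st$relation, change(st$object))
  else st
}

#' Derive a perturbed prediction corpus with known expected counts
#'
#' Each gold statement is assigned at most one perturbation operator
#' (operators therefore act on disjoint statement subsets); the expected
#' per-level confusion counts of the resulting gold/prediction pair are
#' computed with the reference matcher [bel_oracle_match()], not with the
#' production scorer, so they can serve as ground truth for end-to-end
#' tests.
#'
#' @param gold Gold corpus data frame (`evidence_id`, `text`), e.g. from
#'   [bel_sample_corpus()].
#' @param rates Named numeric vector of per-statement operator
#'   probabilities over `swap_entity`, `flip_relation`, `drop_function`,
#'   `change_function`, `insert_placeholder`, `drop_statement`,
#'   `add_spurious`; their sum (plus the implied no-op rate) must be
#'   at most 1.
#' @param config Generator configuration (used by `add_spurious`).
#' @param seed Integer seed.
#' @return Object of class `bel_perturbed_pair`: list with `gold`,
#'   `pred` (both submission data frames), `ops` (operator applied per
#'   gold row) and `expected` (data frame of per-level tp/fp/fn).
#' @export
bel_perturb <- function(gold,
                        rates = c(swap_entity = 0.08, flip_relation = 0.08,
                                  drop_function = 0.08, change_function = 0.05,
                                  insert_placeholder = 0.08,
                                  drop_statement = 0.05, add_spurious = 0.05),
                        config = bel_synth_config(), seed = 1) {
  stopifnot(all(names(rates) %in% .BEL_PERTURB_OPS), all(rates >= 0),
            sum(rates) <= 1)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  ops_all <- c(names(rates), "none")
  w <- c(unname(rates), 1 - sum(rates))
  pred_ids <- character(0); pred_texts <- character(0)
  ops <- character(nrow(gold))
  for (r in seq_len(nrow(gold))) {
    st <- bel_parse(gold$text[r])
    op <- .draw(ops_all, w)
    ops[r] <- op
    out <- switch(op,
      none = list(st),
      swap_entity = list(.op_swap_entity(st, config)),
      flip_relation = list(.op_flip_relation(st, config)),
      drop_function = list(.op_drop_function(st, config)),
      change_function = list(.op_change_function(st, config)),
      insert_placeholder = list(.op_insert_placeholder(st, config)),
      drop_statement = list(),
      add_spurious = list(st, bel_sample_statement(config)))
    for (s in out) {
      pred_ids <- c(pred_ids, gold$evidence_id[r])
      pred_texts <- c(pred_texts, bel_render(s))
    }
  }
  pred <- data.frame(evidence_id = pred_ids, text = pred_texts,
                     stringsAsFactors = FALSE)
  expected <- .expected_counts(gold, pred)
  structure(list(gold = gold, pred = pred, ops = ops, expected = expected),
            class = "bel_perturbed_pair")
}

# expected per-level counts via the reference matcher
.expected_counts <- function(gold, pred, eq = bel_equivalence()) {
  ids <- unique(c(gold$evidence_id, pred$evidence_id))
  tot <- matrix(0L, length(bel_levels()), 3,
                dimnames = list(bel_levels(), c("tp", "fp", "fn")))
  for (id in ids) {
    g <- .pool_fragments(lapply(gold$text[gold$evidence_id == id],
                                function(tx) bel_simplify(bel_parse(tx), eq)))
    p <- .pool_fragments(lapply(pred$text[pred$evidence_id == id],
                                function(tx) bel_simplify(bel_parse(tx), eq)))
    for (lv in bel_levels()) {
      m <- bel_oracle_match(g[[lv]], p[[lv]], lv)
      tot[lv, ] <- tot[lv, ] + c(m$tp, m$fp, m$fn)
    }
  }
  data.frame(level = rownames(tot), tp = tot[, "tp"], fp = tot[, "fp"],
             fn = tot[, "fn"], row.names = NULL, stringsAsFactors = FALSE)
}

#' Generate synthetic ranked relevance judgments
#'
#' Emulates the shape of the manually judged retrieval output: up to 10
#' evidences per statement (list length drawn from a normal with mean
#' 8.3 and standard deviation 3, clamped to 1..10), labels drawn with
#' roughly one third of items fully supportive.
#'
#' @param n_statements Number of BEL statements (queries).
#' @param seed Integer seed.
#' @param label_probs Probabilities of the labels `full`, `relaxed`,
#'   `context`, `negative`, in that order.
#' @return A `bel_judgments` data frame (see [bel_read_judgments()]).
#' @export
bel_sample_judgments <- function(n_statements = 96, seed = 1,
                                 label_probs = c(0.35, 0.15, 0.10, 0.40)) {
  stopifnot(length(label_probs) == 4L, all(label_probs >= 0))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  rows <- lapply(seq_len(n_statements), function(i) {
    n <- max(1L, min(10L, round(stats::rnorm(1, 8.3, 3))))
    data.frame(
      statement_id = sprintf("bel%03d", i),
      rank = seq_len(n),
      evidence_id = sprintf("bel%03d_ev%02d", i, seq_len(n)),
      label = sample(.JUDGMENT_LABELS, n, replace = TRUE, prob = label_probs),
      sentence_count = sample(1:2, n, replace = TRUE),
      stringsAsFactors = FALSE
    )
  })
  df <- do.call(rbind, rows)
  class(df) <- c("bel_judgments", "data.frame")
  df
}
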