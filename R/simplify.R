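# Evaluation simplifications. All scoring is performed on simplified
# statements; the four rules make the comparison liberal where the gold
# annotation carries more detail than a system can be expected to recover:
#   1. entity mapping through an equivalence table (identity fallback);
#   2. the activity functions kin(), tscript() and cat() collapse to act();
#   3. pmod() keeps only its modification type (residue and position are
#      dropped) and tloc() loses its location arguments;
#   4. directlyIncreases/directlyDecreases merge with increases/decreases.
# In addition, complex() member terms and the two arguments of the
# symmetric association relation are ordered lexicographically so that
# rendered forms are canonical under set semantics.

.simplify_term <- function(term, eq) {
  entity <- .map_entity(term$entity, eq)
  mods <- lapply(term$mods, function(m) list(kind = m$kind, args = m$args[1]))
  bel_term(term$fn, entity, mods)
}

.simplify_fterm <- function(ft, eq) {
  wrapper <- ft$wrapper
  if (wrapper %in% .BEL_ACT_FAMILY) wrapper <- "act"
  terms <- lapply(ft$terms, .simplify_term, eq = eq)
  if (identical(wrapper, "complex") && length(terms) > 1L)
    terms <- terms[order(vapply(terms, .render_term, character(1)))]
  bel_fterm(wrapper, terms, extra = character(0))  # tloc locations dropped
}

#' Apply the evaluation simplifications to a statement
#'
#' Produces the normalized form on which all cascade comparisons are
#' made: entities are replaced by their canonical equivalents, the
#' activity functions `kin`/`tscript`/`cat` become `act`, `pmod()` is
#' reduced to its modification type, `tloc()` location arguments are
#' dropped, and `directlyIncreases`/`directlyDecreases` become
#' `increases`/`decreases`. `complex()` members are sorted
#' lexicographically, and the two arguments of the symmetric
#' `association` relation are put in lexicographic order. The operation
#' is idempotent.
#'
#' @param statement A [bel_statement()].
#' @param eq A [bel_equivalence()]; default is the identity table.
#' @return A simplified `bel_statement`.
#' @examples
#' s <- bel_parse("cat(p(HGNC:FAS)) -> p(HGNC:RB1,pmod(P,S,15))")
#' bel_render(bel_simplify(s))
#' @export
bel_simplify <- function(statement, eq = bel_equivalence()) {
  stopifnot(inherits(statement, "bel_statement"))
  subject <- .simplify_fterm(statement$subject, eq)
  relation <- switch(statement$relation,
                     "=>" = "->", "=|" = "-|", statement$relation)
  object <- if (inherits(statement$object, "bel_statement"))
    bel_simplify(statement$object, eq)
  else .simplify_fterm(statement$object, eq)
  if (identical(relation, "--") && !inherits(object, "bel_statement")) {
    a <- .render_fterm(subject); b <- .render_fterm(object)
    if (b < a) { tmp <- subject; subject <- object; object <- tmp }
  }
  bel_statement(subject, relation, object)
}
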