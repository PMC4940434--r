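# Canonical string rendering: short-form functions and relations, single
# spaces around the relation, no space after commas, values quoted with
# single quotes iff they contain characters outside [A-Za-z0-9_.].

.needs_quote <- function(value) grepl("[^A-Za-z0-9_.]", value)

.render_value <- function(value) {
  if (.needs_quote(value)) sprintf("'%s'", value) else value
}

.render_entity <- function(e) sprintf("%s:%s", e$ns, .render_value(e$value))

.render_term <- function(term, with_mods = TRUE) {
  inner <- .render_entity(term$entity)
  if (with_mods && length(term$mods) > 0L) {
    mods <- vapply(term$mods, function(m)
      sprintf("%s(%s)", m$kind,
              paste(vapply(m$args, .render_value, character(1)), collapse = ",")),
      character(1))
    inner <- paste(c(inner, mods), collapse = ",")
  }
  sprintf("%s(%s)", term$fn, inner)
}

.render_fterm <- function(ft, with_mods = TRUE) {
  terms <- vapply(ft$terms, .render_term, character(1), with_mods = with_mods)
  if (identical(ft$wrapper, "none")) return(terms[[1]])
  args <- paste(c(terms, ft$extra), collapse = ",")
  sprintf("%s(%s)", ft$wrapper, args)
}

#' Render a BEL object to its canonical string
#'
#' Produces the canonical short-form string: short function and relation
#' names, one space on each side of the relation, no spaces after commas,
#' entity values single-quoted iff they contain non-alphanumeric
#' characters, nested statements parenthesized. Rendering then re-parsing
#' is the identity on the AST.
#'
#' @param x A `bel_statement`, `bel_fterm`, `bel_term` or `bel_entity`.
#' @return A character scalar.
#' @examples
#' bel_render(bel_parse("proteinAbundance(HGNC:VEGFA) directlyIncreases act(p(HGNC:KDR))"))
#' @export
bel_render <- function(x) UseMethod("bel_render")

#' @export
bel_render.bel_entity <- function(x) .render_entity(x)

#' @export
bel_render.bel_term <- function(x) .render_term(x)

#' @export
bel_render.bel_fterm <- function(x) .render_fterm(x)

#' @export
bel_render.bel_statement <- function(x) {
  obj <- if (inherits(x$object, "bel_statement"))
    sprintf("(%s)", bel_render(x$object))
  else .render_fterm(x$object)
  sprintf("%s %s %s", .render_fterm(x$subject), x$relation, obj)
}

#' @export
print.bel_statement <- function(x, ...) {
  cat("<bel_statement> ", bel_render(x), "\n", sep = "")
  invisible(x)
}

#' @export
print.bel_fterm <- function(x, ...) {
  cat("<bel_fterm> ", bel_render(x), "\n", sep = "")
  invisible(x)
}

#' @export
format.bel_statement <- function(x, ...) bel_render(x)

#' @export
as.character.bel_statement <- function(x, ...) bel_render(x)
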