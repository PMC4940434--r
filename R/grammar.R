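# Recursive-descent parser and validator for the restricted BEL grammar:
# statements of the form  <fterm> <relation> <fterm | nested statement>,
# where a fterm is either a plain term  fn(NS:value[,pmod(...)...])  or a
# wrapper function (act/kin/tscript/cat, deg, tloc, complex) over terms.
# Syntax errors abort immediately; semantic violations (unknown namespace,
# namespace/function incompatibility, arity, misplaced pmod, ...) are
# collected so that a single pass reports every problem in the input.

.bel_validation_error <- function(errors) {
  msg <- paste(vapply(errors, function(e) {
    if (is.na(e$offset)) e$message
    else sprintf("%s (offset %d)", e$message, e$offset)
  }, character(1)), collapse = "; ")
  structure(
    class = c("bel_validation_error", "error", "condition"),
    list(message = msg, call = NULL, errors = errors)
  )
}

#' Construct a BEL entity
#'
#' @param ns Namespace prefix (case-insensitive; canonicalized to upper
#'   case). One of [bel_namespaces()].
#' @param value Identifier string (without surrounding quotes).
#' @return An object of class `bel_entity` with fields `ns`, `value` and
#'   `placeholder` (`TRUE` iff the namespace is `PH`).
#' @export
bel_entity <- function(ns, value) {
  ns <- toupper(ns)
  structure(list(ns = ns, value = value, placeholder = identical(ns, "PH")),
            class = "bel_entity")
}

#' Construct a BEL term
#'
#' @param fn Abundance/process function short form
#'   (`p`, `g`, `r`, `m`, `a`, `bp`, `path`).
#' @param entity A [bel_entity()].
#' @param mods List of modifications; each a list with fields `kind`
#'   (`"pmod"`) and `args` (character vector: type, optional residue,
#'   optional position).
#' @return Object of class `bel_term`.
#' @export
bel_term <- function(fn, entity, mods = list()) {
  structure(list(fn = fn, entity = entity, mods = mods), class = "bel_term")
}

#' Construct a functioned term
#'
#' @param wrapper Wrapper function short form (`act`, `kin`, `tscript`,
#'   `cat`, `deg`, `tloc`, `complex`) or `"none"` for a bare term.
#' @param terms List of [bel_term()] arguments (exactly one except for
#'   `complex`, which takes one or more).
#' @param extra Character vector of verbatim location arguments
#'   (`tloc` only); retained by the parser, ignored by canonicalization.
#' @return Object of class `bel_fterm`.
#' @export
bel_fterm <- function(wrapper = "none", terms, extra = character()) {
  structure(list(wrapper = wrapper, terms = terms, extra = extra),
            class = "bel_fterm")
}

#' Construct a BEL statement
#'
#' @param subject A [bel_fterm()].
#' @param relation Relation in short form (`->`, `-|`, `=>`, `=|`, `--`)
#'   or long form.
#' @param object A [bel_fterm()] or a nested `bel_statement` (one level
#'   of nesting only).
#' @return Object of class `bel_statement`.
#' @export
bel_statement <- function(subject, relation, object) {
  rel <- .relation_short(relation)
  if (is.na(rel)) stop("unknown relation: ", relation)
  structure(list(subject = subject, relation = rel, object = object),
            class = "bel_statement")
}

# ---- parser internals -----------------------------------------------------

.new_parser <- function(tokens) {
  env <- new.env(parent = emptyenv())
  env$tok <- tokens
  env$i <- 1L
  env$errors <- list()
  env
}

.p_peek <- function(p) {
  if (p$i > nrow(p$tok)) NULL else p$tok[p$i, ]
}

.p_next <- function(p) {
  t <- .p_peek(p)
  if (is.null(t)) NULL else { p$i <- p$i + 1L; t }
}

.p_err <- function(p, msg, offset = NA_integer_) {
  p$errors[[length(p$errors) + 1L]] <- list(message = msg, offset = offset)
  invisible(NULL)
}

.p_end_offset <- function(p) {
  if (nrow(p$tok) == 0L) 1L
  else p$tok$pos[nrow(p$tok)] + nchar(p$tok$text[nrow(p$tok)])
}

.p_expect <- function(p, type, what) {
  t <- .p_peek(p)
  if (is.null(t))
    stop(.bel_syntax_error(sprintf("expected %s but input ended", what),
                           .p_end_offset(p)))
  if (t$type != type)
    stop(.bel_syntax_error(sprintf("expected %s but found '%s'", what, t$text),
                           t$pos))
  .p_next(p)
}

# NS:value entity; value is ident or quoted
.p_entity <- function(p) {
  ns_tok <- .p_expect(p, "ident", "namespace prefix")
  ns <- toupper(ns_tok$text)
  if (!ns %in% bel_namespaces())
    .p_err(p, sprintf("unknown namespace '%s'", ns_tok$text), ns_tok$pos)
  .p_expect(p, "colon", "':'")
  v <- .p_peek(p)
  if (is.null(v) || !v$type %in% c("ident", "quoted"))
    stop(.bel_syntax_error("expected entity identifier after ':'",
                           if (is.null(v)) .p_end_offset(p) else v$pos))
  .p_next(p)
  if (!nzchar(v$text))
    .p_err(p, "empty entity identifier", v$pos)
  bel_entity(ns, v$text)
}

# pmod(type[,residue[,position]]) following a comma inside a term
.p_modification <- function(p, host_fn) {
  name_tok <- .p_expect(p, "ident", "modification function")
  kind <- .mod_short(name_tok$text)
  if (is.na(kind)) {
    .p_err(p, sprintf("unsupported modification function '%s'", name_tok$text),
           name_tok$pos)
    kind <- name_tok$text
  } else if (!identical(host_fn, "p")) {
    .p_err(p, "pmod() is only allowed inside a protein term p()",
           name_tok$pos)
  }
  .p_expect(p, "lparen", "'('")
  args <- character(0)
  repeat {
    t <- .p_peek(p)
    if (is.null(t))
      stop(.bel_syntax_error("unterminated modification argument list",
                             .p_end_offset(p)))
    if (!t$type %in% c("ident", "quoted"))
      stop(.bel_syntax_error(
        sprintf("expected modification argument but found '%s'", t$text),
        t$pos))
    args <- c(args, t$text)
    .p_next(p)
    sep <- .p_peek(p)
    if (!is.null(sep) && sep$type == "comma") { .p_next(p); next }
    break
  }
  .p_expect(p, "rparen", "')'")
  if (length(args) == 0L || !nzchar(args[1]))
    .p_err(p, "modification requires a non-empty type argument", name_tok$pos)
  if (length(args) > 3L)
    .p_err(p, "too many arguments in modification (at most type, residue, position)",
           name_tok$pos)
  list(kind = if (is.na(.mod_short(name_tok$text))) kind else "pmod",
       args = args)
}

# plain term: fn(NS:value[,mod]...)
.p_term <- function(p) {
  name_tok <- .p_expect(p, "ident", "abundance function")
  fn <- .abundance_short(name_tok$text)
  if (is.na(fn)) {
    .p_err(p, sprintf("unknown function '%s'", name_tok$text), name_tok$pos)
    fn <- name_tok$text
  }
  .p_expect(p, "lparen", "'('")
  entity <- .p_entity(p)
  mods <- list()
  repeat {
    t <- .p_peek(p)
    if (!is.null(t) && t$type == "comma") {
      .p_next(p)
      mods[[length(mods) + 1L]] <- .p_modification(p, fn)
    } else break
  }
  .p_expect(p, "rparen", "')'")
  if (!entity$placeholder && !is.na(.abundance_short(name_tok$text)) &&
      !.ns_function_ok(entity$ns, fn))
    .p_err(p, sprintf("function %s() is not compatible with namespace %s",
                      fn, entity$ns), name_tok$pos)
  bel_term(fn, entity, mods)
}

# verbatim tloc location argument: tokens up to the next comma/rparen
.p_location <- function(p) {
  parts <- character(0)
  repeat {
    t <- .p_peek(p)
    if (is.null(t))
      stop(.bel_syntax_error("unterminated location argument", .p_end_offset(p)))
    if (t$type %in% c("comma", "rparen")) break
    parts <- c(parts, if (t$type == "quoted") sprintf("'%s'", t$text) else t$text)
    .p_next(p)
  }
  paste(parts, collapse = "")
}

# fterm: wrapper(term...) or plain term
.p_fterm <- function(p) {
  t <- .p_peek(p)
  if (is.null(t))
    stop(.bel_syntax_error("expected a BEL term but input ended",
                           .p_end_offset(p)))
  if (t$type != "ident")
    stop(.bel_syntax_error(sprintf("expected a BEL term but found '%s'", t$text),
                           t$pos))
  wr <- .wrapper_short(t$text)
  if (!is.na(wr)) {
    .p_next(p)
    .p_expect(p, "lparen", "'('")
    terms <- list(.p_term(p))
    extra <- character(0)
    repeat {
      s <- .p_peek(p)
      if (!is.null(s) && s$type == "comma") {
        .p_next(p)
        nxt <- .p_peek(p)
        starts_term <- !is.null(nxt) && nxt$type == "ident" &&
          !is.na(.abundance_short(nxt$text)) &&
          p$i < nrow(p$tok) && p$tok$type[p$i + 1L] == "lparen"
        if (wr == "complex" && starts_term) {
          terms[[length(terms) + 1L]] <- .p_term(p)
        } else if (wr == "tloc") {
          extra <- c(extra, .p_location(p))
        } else if (starts_term) {
          terms[[length(terms) + 1L]] <- .p_term(p)
          .p_err(p, sprintf("%s() takes exactly one BEL term argument", wr),
                 t$pos)
        } else {
          stop(.bel_syntax_error(
            sprintf("unexpected argument in %s() near offset %d", wr,
                    if (is.null(nxt)) .p_end_offset(p) else nxt$pos),
            if (is.null(nxt)) .p_end_offset(p) else nxt$pos))
        }
      } else break
    }
    .p_expect(p, "rparen", "')'")
    return(bel_fterm(wr, terms, extra))
  }
  bel_fterm("none", list(.p_term(p)))
}

.p_relation <- function(p) {
  t <- .p_peek(p)
  if (is.null(t)) {
    .p_err(p, "relation missing", .p_end_offset(p))
    return(NULL)
  }
  if (t$type == "rel") { .p_next(p); return(t$text) }
  if (t$type == "ident") {
    rel <- .relation_short(t$text)
    if (!is.na(rel)) { .p_next(p); return(rel) }
    .p_next(p)
    .p_err(p, sprintf("unknown relation '%s'", t$text), t$pos)
    return("->")  # placeholder so parsing can continue and report more errors
  }
  stop(.bel_syntax_error(sprintf("expected a relation but found '%s'", t$text),
                         t$pos))
}

.p_statement <- function(p, depth = 0L) {
  subject <- .p_fterm(p)
  rel <- .p_relation(p)
  if (is.null(rel)) stop(.bel_validation_error(p$errors))
  t <- .p_peek(p)
  if (!is.null(t) && t$type == "lparen") {
    if (depth >= 1L)
      .p_err(p, "nested statements may not themselves contain nested statements",
             t$pos)
    .p_next(p)
    object <- .p_statement(p, depth + 1L)
    .p_expect(p, "rparen", "')' closing the nested statement")
  } else {
    object <- .p_fterm(p)
    nxt <- .p_peek(p)
    if (!is.null(nxt) && (nxt$type == "rel" ||
        (nxt$type == "ident" && !is.na(.relation_short(nxt$text))))) {
      if (depth >= 1L)
        .p_err(p, "nested statements may not themselves contain nested statements",
               nxt$pos)
      inner_rel <- .p_relation(p)
      inner_obj <- .p_fterm(p)
      object <- bel_statement(object, inner_rel, inner_obj)
    }
  }
  bel_statement(subject, rel, object)
}

# ---- public surface -------------------------------------------------------

#' Parse a BEL statement
#'
#' Parses one statement of the restricted BEL sublanguage into an abstract
#' syntax tree. Long and short function and relation names are
#' interchangeable on input; whitespace between tokens is ignored; a
#' nested statement may appear in object position (optionally
#' parenthesized), at most one level deep.
#'
#' @param text Raw statement string.
#' @return A [bel_statement()].
#' @seealso [bel_validate()] for a non-throwing validation report,
#'   [bel_render()] for the canonical string form.
#' @examples
#' s <- bel_parse("p(MGI:Cav1,pmod(P)) -> a(CHEBI:'nitric oxide')")
#' bel_render(s)
#' @export
bel_parse <- function(text) {
  tokens <- bel_tokenize(text)
  p <- .new_parser(tokens)
  st <- .p_statement(p)
  t <- .p_peek(p)
  if (!is.null(t))
    .p_err(p, sprintf("unexpected trailing input '%s'", t$text), t$pos)
  if (length(p$errors) > 0L) stop(.bel_validation_error(p$errors))
  st
}

#' Parse a single BEL term or functioned term
#'
#' Accepts a bare term such as `p(HGNC:MAPK14)` or a wrapped term such as
#' `act(p(HGNC:MMP9))`, without a relation.
#'
#' @param text Raw term string.
#' @return A [bel_fterm()].
#' @export
bel_parse_term <- function(text) {
  tokens <- bel_tokenize(text)
  p <- .new_parser(tokens)
  ft <- .p_fterm(p)
  t <- .p_peek(p)
  if (!is.null(t))
    .p_err(p, sprintf("unexpected trailing input '%s'", t$text), t$pos)
  if (length(p$errors) > 0L) stop(.bel_validation_error(p$errors))
  ft
}

#' Validate a BEL statement string
#'
#' Never throws: returns a machine-readable report with every syntactic
#' and semantic violation found (unknown namespace or function, arity
#' violation, namespace/function incompatibility, missing relation, ...),
#' each with a character offset where available.
#'
#' @param text Raw statement string.
#' @return A list with elements `ok` (logical) and `errors` (data frame
#'   with columns `message` and `offset`; zero rows when valid).
#' @examples
#' bel_validate("p(HGNC:TIMP1) =| act(p(HGNC:MMP9))")$ok
#' bel_validate("p(HGNC:X) foo p(HGNC:Y)")$errors
#' @export
bel_validate <- function(text) {
  err_df <- function(msgs, offs) {
    data.frame(message = msgs, offset = offs, stringsAsFactors = FALSE)
  }
  res <- tryCatch(
    { bel_parse(text); NULL },
    bel_validation_error = function(e) {
      err_df(vapply(e$errors, `[[`, character(1), "message"),
             vapply(e$errors, function(x) as.integer(x$offset), integer(1)))
    },
    bel_syntax_error = function(e) err_df(conditionMessage(e), as.integer(e$offset)),
    error = function(e) err_df(conditionMessage(e), NA_integer_)
  )
  if (is.null(res)) list(ok = TRUE, errors = err_df(character(0), integer(0)))
  else list(ok = FALSE, errors = res)
}
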