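# Fragment decomposition. A simplified statement is cut into the units
# scored at each cascade level:
#   term                -- every contained term, modifications stripped
#   function            -- wrapper/modification functions with their
#                          argument terms ("primary")
#   function_secondary  -- bare function names
#   relation            -- the (subject, relation, object) triple with all
#                          functions other than complex() discarded
#   relation_secondary  -- same triple, scored two-of-three
#   full                -- the whole canonical statement
# Fragments carry a placeholder flag: a fragment containing a PH entity
# (or, at the relation/full levels, the association relation) can earn a
# false negative but never a false positive.

#' Cascade evaluation levels
#'
#' @return Character vector of the six level names, in cascade order.
#' @export
bel_levels <- function() {
  c("term", "function", "function_secondary",
    "relation", "relation_secondary", "full")
}

.fragment <- function(level, key, placeholder = FALSE, members = NULL,
                      name = NULL, sub = NULL, rel = NULL, obj = NULL,
                      sub_ph = FALSE, obj_ph = FALSE) {
  structure(list(level = level, key = key, placeholder = placeholder,
                 members = members, name = name, sub = sub, rel = rel,
                 obj = obj, sub_ph = sub_ph, obj_ph = obj_ph),
            class = "bel_fragment")
}

# bare term string: modifications stripped
.bare_term <- function(term) .render_term(term, with_mods = FALSE)

# all plain terms contained in a statement (nested statements included)
.collect_terms <- function(statement) {
  fts <- .collect_fterms(statement)
  unlist(lapply(fts, function(ft) ft$terms), recursive = FALSE)
}

# all fterms of a statement, nested statements included
.collect_fterms <- function(statement) {
  obj <- statement$object
  c(list(statement$subject),
    if (inherits(obj, "bel_statement")) .collect_fterms(obj) else list(obj))
}

.any_ph_in_fterm <- function(ft) {
  any(vapply(ft$terms, function(t) t$entity$placeholder, logical(1)))
}

.extract_terms <- function(statement) {
  lapply(.collect_terms(statement), function(t)
    .fragment("term", .bare_term(t), placeholder = t$entity$placeholder))
}

.extract_functions <- function(statement) {
  primary <- list()
  secondary <- list()
  for (ft in .collect_fterms(statement)) {
    if (!identical(ft$wrapper, "none")) {
      ph <- .any_ph_in_fterm(ft)
      members <- if (identical(ft$wrapper, "complex"))
        vapply(ft$terms, .bare_term, character(1)) else NULL
      primary[[length(primary) + 1L]] <-
        .fragment("function", .render_fterm(ft), placeholder = ph,
                  members = members, name = ft$wrapper)
      secondary[[length(secondary) + 1L]] <-
        .fragment("function_secondary", ft$wrapper, name = ft$wrapper)
    }
    for (t in ft$terms) {
      for (m in t$mods) {
        key <- sprintf("%s(%s)@%s", m$kind,
                       paste(vapply(m$args, .render_value, character(1)),
                             collapse = ","),
                       .bare_term(t))
        primary[[length(primary) + 1L]] <-
          .fragment("function", key, placeholder = t$entity$placeholder,
                    name = m$kind)
        secondary[[length(secondary) + 1L]] <-
          .fragment("function_secondary", m$kind, name = m$kind)
      }
    }
  }
  list(primary = primary, secondary = secondary)
}

# function-stripped side of a relation: complex() keeps its member set,
# every other wrapper is discarded down to the bare argument term
.strip_side <- function(ft) {
  if (identical(ft$wrapper, "complex")) {
    members <- vapply(ft$terms, .bare_term, character(1))
    list(key = sprintf("complex(%s)", paste(members, collapse = ",")),
         set = members, ph = .any_ph_in_fterm(ft))
  } else {
    bare <- .bare_term(ft$terms[[1]])
    list(key = bare, set = bare, ph = .any_ph_in_fterm(ft))
  }
}

.extract_relation <- function(statement, level = "relation") {
  sub <- .strip_side(statement$subject)
  obj <- statement$object
  if (inherits(obj, "bel_statement")) {
    inner_sub <- .strip_side(obj$subject)
    inner_obj <- .strip_side(obj$object)
    key <- sprintf("%s %s %s", inner_sub$key, obj$relation, inner_obj$key)
    objc <- list(key = key, set = key,
                 ph = inner_sub$ph || inner_obj$ph ||
                      identical(obj$relation, "--"))
  } else {
    objc <- .strip_side(obj)
  }
  ph <- sub$ph || objc$ph || identical(statement$relation, "--")
  .fragment(level,
            sprintf("%s %s %s", sub$key, statement$relation, objc$key),
            placeholder = ph, sub = sub$set, rel = statement$relation,
            obj = objc$set, sub_ph = sub$ph, obj_ph = objc$ph)
}

.statement_has_ph <- function(statement) {
  any(vapply(.collect_terms(statement),
             function(t) t$entity$placeholder, logical(1)))
}

.statement_has_assoc <- function(statement) {
  identical(statement$relation, "--") ||
    (inherits(statement$object, "bel_statement") &&
       .statement_has_assoc(statement$object))
}

.extract_full <- function(statement) {
  .fragment("full", bel_render(statement),
            placeholder = .statement_has_ph(statement) ||
                          .statement_has_assoc(statement))
}

#' Decompose a simplified statement into its cascade fragments
#'
#' @param statement A [bel_statement()], normally already passed through
#'   [bel_simplify()] (the function does not simplify for you, so that
#'   the decomposition itself stays inspectable).
#' @return Named list over [bel_levels()]; each element is a list of
#'   fragment records with fields `level`, `key` (canonical string),
#'   `placeholder`, and for relation fragments the triple components
#'   (`sub`, `rel`, `obj`; a `complex()` side is its member-term set).
#' @examples
#' fr <- bel_fragments(bel_simplify(bel_parse("act(p(MGI:Hras)) -> p(MGI:Mmp9)")))
#' sapply(fr$term, `[[`, "key")
#' fr$`function`[[1]]$key
#' @export
bel_fragments <- function(statement) {
  stopifnot(inherits(statement, "bel_statement"))
  fn <- .extract_functions(statement)
  list(
    term                = .extract_terms(statement),
    `function`          = fn$primary,
    function_secondary  = fn$secondary,
    relation            = list(.extract_relation(statement, "relation")),
    relation_secondary  = list(.extract_relation(statement, "relation_secondary")),
    full                = list(.extract_full(statement))
  )
}

# pool fragments of several statements into one per-level multiset
.pool_fragments <- function(statements) {
  pools <- stats::setNames(vector("list", length(bel_levels())), bel_levels())
  for (lv in bel_levels()) pools[[lv]] <- list()
  for (s in statements) {
    fr <- bel_fragments(s)
    for (lv in bel_levels()) pools[[lv]] <- c(pools[[lv]], fr[[lv]])
  }
  pools
}
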