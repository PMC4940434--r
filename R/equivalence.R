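# Entity equivalence tables: map (namespace, identifier) pairs onto a
# canonical entity key so that, e.g., mouse MGI symbols and EGID numeric
# identifiers score as equal to their human HGNC counterpart. The mapping
# is total by identity fallback: an entity without a table entry maps to
# itself.

#' Construct an entity equivalence table
#'
#' @param mapping Named character vector: names are source entities in
#'   `PREFIX:value` form, values are canonical targets in `PREFIX:value`
#'   form. May be empty (identity table).
#' @param mgi_uppercase Heuristic fallback mapping MGI symbols to the
#'   upper-cased symbol under HGNC (mouse gene symbols differ from their
#'   human orthologs mostly by case). Off by default; only consulted for
#'   entities absent from `mapping`.
#' @param provenance Source description (e.g. file name) carried along
#'   for reports.
#' @return Object of class `bel_equivalence`.
#' @export
bel_equivalence <- function(mapping = character(0), mgi_uppercase = FALSE,
                            provenance = "identity") {
  if (length(mapping) > 0L && is.null(names(mapping)))
    stop("mapping must be a named character vector")
  structure(list(mapping = mapping, mgi_uppercase = isTRUE(mgi_uppercase),
                 provenance = provenance),
            class = "bel_equivalence")
}

.split_entity_key <- function(key, where = "") {
  m <- regmatches(key, regexec("^([A-Za-z]+):(.+)$", key))[[1]]
  if (length(m) != 3L)
    stop(sprintf("malformed entity key '%s'%s (expected PREFIX:value)", key, where))
  ns <- toupper(m[2])
  if (!ns %in% bel_namespaces())
    stop(sprintf("unknown namespace in entity key '%s'%s", key, where))
  list(ns = ns, value = m[3])
}

#' Load an entity equivalence table from a tab-separated file
#'
#' Each data line has two columns: a source entity `PREFIX:value` and its
#' canonical target `PREFIX:value`. Lines starting with `#` and blank
#' lines are skipped. Quoting of values is optional and stripped.
#' Duplicate sources pointing at different targets are an error.
#'
#' @param path Path to the TSV file (UTF-8).
#' @return A [bel_equivalence()].
#' @export
bel_read_equivalences <- function(path) {
  if (!file.exists(path)) stop("equivalence file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  mapping <- character(0)
  for (i in seq_along(lines)) {
    line <- trimws(lines[i])
    if (!nzchar(line) || startsWith(line, "#")) next
    fields <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (length(fields) < 2L)
      stop(sprintf("line %d: expected 2 tab-separated columns", i))
    strip <- function(x) gsub("^['\"]|['\"]$", "", trimws(x))
    src <- .split_entity_key(.normalize_unicode(strip(fields[1])),
                             sprintf(" at line %d", i))
    tgt <- .split_entity_key(.normalize_unicode(strip(fields[2])),
                             sprintf(" at line %d", i))
    src_key <- sprintf("%s:%s", src$ns, src$value)
    tgt_key <- sprintf("%s:%s", tgt$ns, tgt$value)
    if (src_key %in% names(mapping) && !identical(unname(mapping[src_key]), tgt_key))
      stop(sprintf("line %d: conflicting duplicate mapping for %s", i, src_key))
    mapping[src_key] <- tgt_key
  }
  bel_equivalence(mapping, provenance = basename(path))
}

# canonical entity for one bel_entity under a table (identity fallback)
.map_entity <- function(entity, eq) {
  if (entity$placeholder) return(entity)
  key <- sprintf("%s:%s", entity$ns, entity$value)
  if (key %in% names(eq$mapping)) {
    tgt <- .split_entity_key(unname(eq$mapping[key]))
    return(bel_entity(tgt$ns, tgt$value))
  }
  if (eq$mgi_uppercase && identical(entity$ns, "MGI"))
    return(bel_entity("HGNC", toupper(entity$value)))
  entity
}
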