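# Controlled vocabularies for the restricted BEL sublanguage: the six
# entity namespaces (plus the PH placeholder namespace), the abundance /
# process functions with their long forms and namespace compatibilities,
# the modifying functions, and the five relationship types.

#' Namespaces accepted by the restricted BEL grammar
#'
#' The sublanguage admits six controlled-vocabulary namespaces (HGNC, MGI,
#' EGID, GOBP, MESHD, CHEBI) plus the special `PH` placeholder namespace
#' used for dummy entities of the form `PH:placeholder`. Prefix matching
#' is case-insensitive; the canonical form is upper case.
#'
#' @return Character vector of canonical namespace prefixes.
#' @export
bel_namespaces <- function() {
  c("HGNC", "MGI", "EGID", "GOBP", "MESHD", "CHEBI", "PH")
}

# abundance/process functions: short form -> long form
.BEL_ABUNDANCE_LONG <- c(
  p    = "proteinAbundance",
  g    = "geneAbundance",
  r    = "rnaAbundance",
  m    = "microRNAAbundance",
  a    = "abundance",
  bp   = "biologicalProcess",
  path = "pathology"
)

# wrapper ("modifying") functions: short form -> long form
.BEL_WRAPPER_LONG <- c(
  act     = "molecularActivity",
  kin     = "kinaseActivity",
  tscript = "transcriptionalActivity",
  cat     = "catalyticActivity",
  deg     = "degradation",
  tloc    = "translocation",
  complex = "complexAbundance"
)

.BEL_MOD_LONG <- c(pmod = "proteinModification")

# activity family collapsed to act() during evaluation simplification
.BEL_ACT_FAMILY <- c("act", "kin", "tscript", "cat")

# namespace -> admissible abundance functions (PH is compatible with all)
.BEL_NS_FUNCTIONS <- list(
  HGNC  = c("p", "g", "r", "m"),
  MGI   = c("p", "g", "r", "m"),
  EGID  = c("p", "g", "r"),
  GOBP  = "bp",
  MESHD = "path",
  CHEBI = "a",
  PH    = c("p", "g", "r", "m", "a", "bp", "path")
)

# relations: long form -> short symbol
.BEL_RELATION_SHORT <- c(
  increases         = "->",
  decreases         = "-|",
  directlyIncreases = "=>",
  directlyDecreases = "=|",
  association       = "--"
)

#' Relationship types of the restricted BEL grammar
#'
#' @return Named character vector mapping long relation names to their
#'   short symbols (`increases` = `->`, `decreases` = `-|`,
#'   `directlyIncreases` = `=>`, `directlyDecreases` = `=|`,
#'   `association` = `--`).
#' @export
bel_relations <- function() .BEL_RELATION_SHORT

# short-form lookup helpers (long or short input -> short form, NA if unknown)
.abundance_short <- function(x) {
  if (x %in% names(.BEL_ABUNDANCE_LONG)) return(x)
  hit <- names(.BEL_ABUNDANCE_LONG)[match(x, .BEL_ABUNDANCE_LONG)]
  if (length(hit) == 1L && !is.na(hit)) hit else NA_character_
}

.wrapper_short <- function(x) {
  if (x %in% names(.BEL_WRAPPER_LONG)) return(x)
  hit <- names(.BEL_WRAPPER_LONG)[match(x, .BEL_WRAPPER_LONG)]
  if (length(hit) == 1L && !is.na(hit)) hit else NA_character_
}

.mod_short <- function(x) {
  if (x %in% names(.BEL_MOD_LONG)) return(x)
  hit <- names(.BEL_MOD_LONG)[match(x, .BEL_MOD_LONG)]
  if (length(hit) == 1L && !is.na(hit)) hit else NA_character_
}

.relation_short <- function(x) {
  if (x %in% .BEL_RELATION_SHORT) return(x)
  if (x %in% names(.BEL_RELATION_SHORT)) return(unname(.BEL_RELATION_SHORT[x]))
  NA_character_
}

.relation_long <- function(short) {
  names(.BEL_RELATION_SHORT)[match(short, .BEL_RELATION_SHORT)]
}

# namespace/abundance-function compatibility (short forms)
.ns_function_ok <- function(ns, fn) {
  ns <- toupper(ns)
  if (!ns %in% names(.BEL_NS_FUNCTIONS)) return(FALSE)
  fn %in% .BEL_NS_FUNCTIONS[[ns]]
}
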