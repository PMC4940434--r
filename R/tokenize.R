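# Tokenizer for BEL statement strings. Unicode quote and dash variants are
# normalized to ASCII before segmentation so that typographically mangled
# input (curly quotes, en dashes in relation symbols) still tokenizes.

# typographic character normalization applied to every input string
.normalize_unicode <- function(text) {
  from <- c("‘", "’", "‚", "‛",  # single quotes
            "“", "”", "„", "‟",  # double quotes
            "‐", "‑", "‒", "–", "—", "−")  # dashes
  to <- c(rep("'", 4L), rep('"', 4L), rep("-", 6L))
  for (i in seq_along(from)) text <- gsub(from[i], to[i], text, fixed = TRUE)
  text
}

.bel_syntax_error <- function(msg, offset = NA_integer_) {
  structure(
    class = c("bel_syntax_error", "error", "condition"),
    list(message = msg, call = NULL, offset = offset)
  )
}

#' Tokenize a BEL statement string
#'
#' Splits a raw statement into tokens (identifiers, quoted strings,
#' parentheses, commas, colons and relation symbols), retaining the
#' 1-based character offset of each token for error reporting. Unicode
#' apostrophes, quotation marks and dash variants are normalized to ASCII
#' beforehand, so `p(HGNC:‘X’)` tokenizes like `p(HGNC:'X')`.
#'
#' @param text A single raw BEL statement string.
#' @return A data frame with columns `type` (one of `ident`, `quoted`,
#'   `lparen`, `rparen`, `comma`, `colon`, `rel`), `text` (the token
#'   content; for `quoted` the value without surrounding quotes) and
#'   `pos` (character offset).
#' @examples
#' bel_tokenize("p(HGNC:MAPK14)")
#' @export
bel_tokenize <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  if (is.na(text) || !nzchar(text))
    stop(.bel_syntax_error("empty input", 1L))
  text <- .normalize_unicode(text)
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  n <- length(chars)
  types <- character(0); texts <- character(0); poss <- integer(0)
  push <- function(type, tok, pos) {
    types[[length(types) + 1L]] <<- type
    texts[[length(texts) + 1L]] <<- tok
    poss[[length(poss) + 1L]] <<- pos
  }
  i <- 1L
  ident_chars <- c(LETTERS, letters, 0:9, "_", ".")
  while (i <= n) {
    ch <- chars[i]
    if (ch %in% c(" ", "\t")) { i <- i + 1L; next }
    if (ch == "(") { push("lparen", "(", i); i <- i + 1L; next }
    if (ch == ")") { push("rparen", ")", i); i <- i + 1L; next }
    if (ch == ",") { push("comma", ",", i); i <- i + 1L; next }
    if (ch == ":") { push("colon", ":", i); i <- i + 1L; next }
    if (ch %in% c("'", '"')) {
      j <- i + 1L
      while (j <= n && chars[j] != ch) j <- j + 1L
      if (j > n)
        stop(.bel_syntax_error(sprintf("unterminated quote starting at offset %d", i), i))
      push("quoted", paste(chars[seq(i + 1L, length.out = j - i - 1L)], collapse = ""), i)
      i <- j + 1L
      next
    }
    if (ch %in% c("-", "=")) {
      nxt <- if (i < n) chars[i + 1L] else ""
      tok <- paste0(ch, nxt)
      if (tok %in% c("->", "-|", "=>", "=|", "--")) {
        push("rel", tok, i); i <- i + 2L; next
      }
      if (ch == "-") {  # lone dash accepted as the association symbol
        push("rel", "--", i); i <- i + 1L; next
      }
      stop(.bel_syntax_error(sprintf("unexpected character '%s' at offset %d", ch, i), i))
    }
    if (ch %in% ident_chars) {
      j <- i
      while (j <= n && chars[j] %in% ident_chars) j <- j + 1L
      push("ident", paste(chars[i:(j - 1L)], collapse = ""), i)
      i <- j
      next
    }
    stop(.bel_syntax_error(sprintf("unexpected character '%s' at offset %d", ch, i), i))
  }
  if (length(types) == 0L)
    stop(.bel_syntax_error("empty input", 1L))
  data.frame(type = types, text = texts, pos = poss, stringsAsFactors = FALSE)
}
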