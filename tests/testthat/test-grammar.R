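test_that("tokenizer segments identifiers, quotes and relation symbols", {
  tk <- bel_tokenize("p(HGNC:MAPK14)")
  expect_equal(tk$type, c("ident", "lparen", "ident", "colon", "ident", "rparen"))
  expect_equal(tk$text[c(1, 3, 5)], c("p", "HGNC", "MAPK14"))

  tk <- bel_tokenize("a(CHEBI:'nitric oxide')")
  expect_equal(tk$text[tk$type == "quoted"], "nitric oxide")

  tk <- bel_tokenize("p(HGNC:X) -> p(HGNC:Y)")
  expect_equal(tk$text[tk$type == "rel"], "->")

  # typographic quotes normalize to ASCII before segmentation
  tk <- bel_tokenize("a(CHEBI:‘nitric oxide’)")
  expect_equal(tk$text[tk$type == "quoted"], "nitric oxide")

  expect_error(bel_tokenize("a(CHEBI:'nitric oxide)"), "unterminated quote")
  expect_error(bel_tokenize(""), "empty input")
})

test_that("parser builds the expected AST for a modified-protein statement", {
  s <- bel_parse("p(MGI:Cav1,pmod(P)) -> a(CHEBI:'nitric oxide')")
  expect_s3_class(s, "bel_statement")
  expect_equal(s$relation, "->")
  subj <- s$subject
  expect_equal(subj$wrapper, "none")
  expect_equal(subj$terms[[1]]$fn, "p")
  expect_equal(subj$terms[[1]]$entity$ns, "MGI")
  expect_equal(subj$terms[[1]]$entity$value, "Cav1")
  expect_equal(subj$terms[[1]]$mods[[1]]$kind, "pmod")
  expect_equal(subj$terms[[1]]$mods[[1]]$args, "P")
  expect_equal(s$object$terms[[1]]$fn, "a")
  expect_equal(s$object$terms[[1]]$entity$value, "nitric oxide")
})

test_that("long and short forms parse to identical ASTs", {
  for (pair in long_short_pairs) {
    expect_identical(bel_parse(pair[1]), bel_parse(pair[2]), info = pair[1])
  }
})

test_that("namespace prefixes are case-insensitive, entity values are not", {
  expect_identical(bel_parse("p(hgnc:MAPK14) -> p(HGNC:TP53)"),
                   bel_parse("p(HGNC:MAPK14) -> p(HGNC:TP53)"))
  expect_false(identical(bel_parse("p(HGNC:ABC1) -> p(HGNC:TP53)"),
                         bel_parse("p(HGNC:abc1) -> p(HGNC:TP53)")))
})

test_that("namespace/function compatibility is enforced per the vocabulary table", {
  ok_cases <- c(
    p = "HGNC", p = "MGI", p = "EGID", g = "HGNC", r = "EGID", m = "HGNC",
    m = "MGI", bp = "GOBP", path = "MESHD", a = "CHEBI"
  )
  for (i in seq_along(ok_cases)) {
    txt <- sprintf("%s(%s:x1) -> p(HGNC:TP53)", names(ok_cases)[i], ok_cases[i])
    expect_true(bel_validate(txt)$ok, info = txt)
  }
  bad_cases <- c(
    bp = "HGNC", bp = "CHEBI", path = "GOBP", a = "HGNC", p = "GOBP",
    p = "CHEBI", m = "EGID", g = "MESHD"
  )
  for (i in seq_along(bad_cases)) {
    txt <- sprintf("%s(%s:x1) -> p(HGNC:TP53)", names(bad_cases)[i], bad_cases[i])
    v <- bel_validate(txt)
    expect_false(v$ok, info = txt)
    expect_match(v$errors$message[1], "not compatible", info = txt)
  }
  # the placeholder namespace is compatible with every abundance function
  for (fn in c("p", "g", "r", "m", "a", "bp", "path")) {
    txt <- sprintf("%s(PH:placeholder) -> p(HGNC:TP53)", fn)
    expect_true(bel_validate(txt)$ok, info = txt)
  }
})

test_that("validator reports structured errors and never raises", {
  expect_true(bel_validate("p(HGNC:TIMP1) =| act(p(HGNC:MMP9))")$ok)

  v <- bel_validate("")
  expect_false(v$ok)
  expect_match(v$errors$message, "empty")

  v <- bel_validate("p(HGNC:X) foo p(HGNC:Y)")
  expect_false(v$ok)
  expect_match(v$errors$message, "unknown relation 'foo'")
  expect_equal(v$errors$offset, 11L)

  v <- bel_validate("p(HGNC:MAPK14")
  expect_false(v$ok)
  expect_equal(v$errors$offset, 14L)

  v <- bel_validate("p(XYZ:A) -> q(HGNC:B)")
  expect_false(v$ok)
  expect_true(any(grepl("unknown namespace", v$errors$message)))
  expect_true(any(grepl("unknown function", v$errors$message)))

  v <- bel_validate("p(HGNC:A)")
  expect_false(v$ok)
  expect_match(v$errors$message, "relation missing")

  # pmod outside a protein term is rejected
  expect_false(bel_validate("g(HGNC:A,pmod(P)) -> p(HGNC:B)")$ok)
  # act takes exactly one argument term
  expect_false(bel_validate("act(p(HGNC:A),p(HGNC:B)) -> p(HGNC:C)")$ok)
})

test_that("parse and validate accept and reject the same strings", {
  cases <- c(table_statements,
             "p(HGNC:X) foo p(HGNC:Y)", "bp(HGNC:MAPK14) -> p(HGNC:TP53)",
             "p(HGNC:MAPK14", "", "act(p(HGNC:A),p(HGNC:B)) -> p(HGNC:C)")
  for (txt in cases) {
    parse_ok <- !inherits(tryCatch(bel_parse(txt), error = identity), "error")
    expect_equal(bel_validate(txt)$ok, parse_ok, info = txt)
  }
})

test_that("rendering is canonical and round-trips", {
  s <- bel_parse("proteinAbundance(HGNC:VEGFA) directlyIncreases act(p(HGNC:KDR))")
  expect_equal(bel_render(s), "p(HGNC:VEGFA) => act(p(HGNC:KDR))")
  # whitespace-insensitivity between tokens
  expect_equal(bel_render(bel_parse("p( HGNC : VEGFA )=>act( p( HGNC:KDR ) )")),
               "p(HGNC:VEGFA) => act(p(HGNC:KDR))")
  for (txt in table_statements) {
    s <- bel_parse(txt)
    expect_identical(bel_parse(bel_render(s)), s, info = txt)
  }
})

test_that("nested statements are accepted in object position, one level deep", {
  a <- bel_parse("p(HGNC:TP53) -> (p(HGNC:MMP9) -| bp(GOBP:'apoptotic process'))")
  b <- bel_parse("p(HGNC:TP53) -> p(HGNC:MMP9) -| bp(GOBP:'apoptotic process')")
  expect_identical(a, b)
  expect_s3_class(a$object, "bel_statement")
  expect_identical(bel_parse(bel_render(a)), a)
  expect_false(bel_validate(
    "p(HGNC:A) -> (p(HGNC:B) -> (p(HGNC:C) -> p(HGNC:D)))")$ok)
})

test_that("generated statements round-trip through render and parse", {
  set.seed(401)
  cfg <- bel_synth_config(n_evidences = 1)
  for (i in 1:60) {
    s <- bel_sample_statement(cfg)
    txt <- bel_render(s)
    expect_true(bel_validate(txt)$ok, info = txt)
    expect_identical(bel_render(bel_parse(txt)), txt, info = txt)
  }
})
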