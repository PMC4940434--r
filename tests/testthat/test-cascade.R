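pool1 <- function(text) {
  belscore:::.pool_fragments(list(bel_simplify(bel_parse(text))))
}

test_that("identical fragment multisets score all true positives", {
  g <- pool1("act(p(MGI:Hras)) -> p(MGI:Mmp9)")
  for (lv in bel_levels()) {
    m <- bel_match_level(g[[lv]], g[[lv]], lv)
    expect_equal(m$fp, 0L)
    expect_equal(m$fn, 0L)
    expect_equal(m$tp, length(g[[lv]]))
  }
})

test_that("placeholder predictions count as false negatives but never false positives", {
  g <- pool1("p(HGNC:TIMP1) -> p(HGNC:MMP9)")
  p <- pool1("p(PH:placeholder) -> p(HGNC:MMP9)")
  m <- bel_match_level(g$term, p$term, "term")
  expect_equal(c(m$tp, m$fp, m$fn), c(1L, 0L, 1L))  # MMP9 matches, TIMP1 is FN only
  m <- bel_match_level(g$relation, p$relation, "relation")
  expect_equal(c(m$tp, m$fp, m$fn), c(0L, 0L, 1L))
  m <- bel_match_level(g$relation_secondary, p$relation_secondary, "relation_secondary")
  expect_equal(c(m$tp, m$fp, m$fn), c(0L, 0L, 1L))
  m <- bel_match_level(g$full, p$full, "full")
  expect_equal(c(m$tp, m$fp, m$fn), c(0L, 0L, 1L))
})

test_that("relation matching follows the three-component truth table", {
  gold <- pool1("p(HGNC:A) -> p(HGNC:B)")
  mk_pred <- function(sub_ok, rel_ok, obj_ok) {
    pool1(sprintf("p(HGNC:%s) %s p(HGNC:%s)",
                  if (sub_ok) "A" else "X",
                  if (rel_ok) "->" else "-|",
                  if (obj_ok) "B" else "Y"))
  }
  for (sub_ok in c(TRUE, FALSE)) for (rel_ok in c(TRUE, FALSE))
    for (obj_ok in c(TRUE, FALSE)) {
      pred <- mk_pred(sub_ok, rel_ok, obj_ok)
      n_ok <- sum(sub_ok, rel_ok, obj_ok)
      mp <- bel_match_level(gold$relation, pred$relation, "relation")
      expect_equal(mp$tp, as.integer(n_ok == 3L), info = paste(sub_ok, rel_ok, obj_ok))
      expect_equal(mp$fp, as.integer(n_ok < 3L))
      ms <- bel_match_level(gold$relation_secondary, pred$relation_secondary,
                            "relation_secondary")
      expect_equal(ms$tp, as.integer(n_ok >= 2L), info = paste(sub_ok, rel_ok, obj_ok))
      expect_equal(ms$fp, as.integer(n_ok < 2L))
      expect_equal(ms$fn, as.integer(n_ok < 2L))
    }
})

test_that("association predictions score only with both arguments correct, never as FP", {
  gold <- pool1("p(HGNC:A) -> p(HGNC:B)")
  both <- pool1("p(HGNC:A) -- p(HGNC:B)")
  m <- bel_match_level(gold$relation_secondary, both$relation_secondary,
                       "relation_secondary")
  expect_equal(c(m$tp, m$fp, m$fn), c(1L, 0L, 0L))
  # at the primary level the unknown relation type blocks credit but adds no FP
  m <- bel_match_level(gold$relation, both$relation, "relation")
  expect_equal(c(m$tp, m$fp, m$fn), c(0L, 0L, 1L))
  # one correct argument only: placeholder-backed, FN but no FP
  one <- pool1("p(HGNC:A) -- p(HGNC:Y)")
  m <- bel_match_level(gold$relation_secondary, one$relation_secondary,
                       "relation_secondary")
  expect_equal(c(m$tp, m$fp, m$fn), c(0L, 0L, 1L))
})

test_that("complex() earns partial credit on one shared member", {
  g <- pool1("complex(p(MGI:Cckbr),p(MGI:Gast)) -> act(p(MGI:Prkd1))")
  p <- pool1("complex(p(MGI:Cckbr),p(MGI:Itga8)) -> act(p(MGI:Prkd1))")
  m <- bel_match_level(g$`function`, p$`function`, "function")
  expect_equal(m$tp, 2L)  # the complex (shared member) and the exact act()
  expect_equal(c(m$fp, m$fn), c(0L, 0L))
  # one shared member in a correct relationship suffices at the primary level
  m <- bel_match_level(g$relation, p$relation, "relation")
  expect_equal(c(m$tp, m$fp, m$fn), c(1L, 0L, 0L))
  # no shared member: no credit
  q <- pool1("complex(p(MGI:Itgb1),p(MGI:Itga8)) -> act(p(MGI:Prkd1))")
  m <- bel_match_level(g$`function`, q$`function`, "function")
  expect_equal(c(m$tp, m$fp, m$fn), c(1L, 1L, 1L))
})

test_that("a placeholder argument blocks primary function credit without FP", {
  g <- pool1("act(p(MGI:Hras)) -> p(MGI:Mmp9)")
  p <- pool1("act(p(PH:placeholder)) -> p(MGI:Mmp9)")
  m <- bel_match_level(g$`function`, p$`function`, "function")
  expect_equal(c(m$tp, m$fp, m$fn), c(0L, 0L, 1L))
  # the bare function name still scores at the secondary level
  m <- bel_match_level(g$function_secondary, p$function_secondary,
                       "function_secondary")
  expect_equal(c(m$tp, m$fp, m$fn), c(1L, 0L, 0L))
})

test_that("mixed-level input is rejected", {
  g <- pool1("p(HGNC:A) -> p(HGNC:B)")
  expect_error(bel_match_level(g$term, g$full, "term"), "level")
})

test_that("evidence scoring matches the worked cascade example", {
  r <- bel_score_evidence("act(p(MGI:Hras)) -> p(MGI:Mmp9)",
                          "p(MGI:Hras) -> p(MGI:Mmp9)")
  expect_equal(c(r$levels$full$tp, r$levels$full$fp, r$levels$full$fn),
               c(0L, 1L, 1L))
  expect_equal(r$levels$relation$tp, 1L)
  expect_equal(c(r$levels$`function`$fn, r$levels$`function`$fp), c(1L, 0L))
  expect_equal(r$levels$term$tp, 2L)

  # identical gold and prediction: perfect scores where fragments exist
  r <- bel_score_evidence("p(HGNC:BCL2A1) -| bp(GOBP:'apoptotic process')",
                          "p(HGNC:BCL2A1) -| bp(GOBP:'apoptotic process')")
  expect_equal(r$levels$term$metrics$f, 1)
  expect_equal(r$levels$full$metrics$f, 1)
  expect_equal(c(r$levels$`function`$tp, r$levels$`function`$fp,
                 r$levels$`function`$fn), c(0L, 0L, 0L))

  # empty prediction list: no FP anywhere, all gold fragments FN
  r <- bel_score_evidence("act(p(MGI:Hras)) -> p(MGI:Mmp9)", character(0))
  for (lv in bel_levels()) {
    expect_equal(r$levels[[lv]]$fp, 0L)
    expect_equal(r$levels[[lv]]$tp, 0L)
  }
  expect_equal(r$levels$term$fn, 2L)
})

test_that("invalid predicted statements are rejected and excluded from counts", {
  r <- bel_score_evidence("p(HGNC:A) -> p(HGNC:B)",
                          c("p(HGNC:A) -> p(HGNC:B)", "bp(HGNC:A) -> p(HGNC:B)"))
  expect_equal(nrow(r$rejected), 1L)
  expect_equal(r$rejected$side, "pred")
  expect_equal(c(r$levels$full$tp, r$levels$full$fp), c(1L, 0L))
})

test_that("aggregation micro-averages counts across evidence texts", {
  mk <- function(tp, fp, fn) {
    lv <- list(list(tp = tp, fp = fp, fn = fn))
    names(lv) <- "full"
    structure(list(evidence_id = "e", levels = lv,
                   rejected = data.frame()), class = "bel_evidence_result")
  }
  rep <- bel_aggregate(list(mk(1, 0, 1), mk(1, 2, 0)))
  expect_equal(rep$overall$full$tp, 2)
  expect_equal(rep$overall$full$fp, 2)
  expect_equal(rep$overall$full$fn, 1)
  expect_equal(bel_percent(rep$overall$full$precision), 50.0)
  expect_equal(bel_percent(rep$overall$full$recall), 66.7)
})

test_that("cascade invariants hold on random perturbed corpora", {
  for (i in 1:50) {
    cfg <- bel_synth_config(n_evidences = 2, statements_max = 2)
    pair <- bel_perturb(bel_sample_corpus(cfg, seed = 500 + i),
                        rates = c(swap_entity = 0.15, flip_relation = 0.15,
                                  insert_placeholder = 0.2, drop_function = 0.1,
                                  add_spurious = 0.1),
                        config = cfg, seed = 900 + i)
    rep <- bel_score_corpus(pair$gold, pair$pred)
    ov <- rep$overall
    # tp + fn equals the number of gold fragments at every level
    for (lv in bel_levels()) {
      expect_equal(ov[[lv]]$tp + ov[[lv]]$fn,
                   gold_fragment_count(pair$gold$text, lv), info = lv)
    }
    # cascade monotonicity
    expect_gte(ov$function_secondary$tp, ov$`function`$tp)
    expect_gte(ov$relation_secondary$tp, ov$relation$tp)
    if (ov$full$tp > 0) expect_gt(ov$relation$tp, 0)
  }
})
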