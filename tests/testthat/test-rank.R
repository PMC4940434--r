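mk_judgments <- function(flags_per_statement) {
  rows <- lapply(seq_along(flags_per_statement), function(i) {
    fl <- flags_per_statement[[i]]
    data.frame(statement_id = sprintf("s%02d", i), rank = seq_along(fl),
               evidence_id = sprintf("s%02d_e%02d", i, seq_along(fl)),
               label = ifelse(fl, "full", "negative"), sentence_count = 1L,
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  class(df) <- c("bel_judgments", "data.frame")
  df
}

test_that("average precision follows its definition", {
  expect_equal(bel_average_precision(c(TRUE, TRUE, TRUE)), 1.0)
  expect_equal(bel_average_precision(c(TRUE, FALSE, TRUE)), (1 + 2/3) / 2)
  expect_equal(bel_average_precision(logical(0)), 0)
  expect_equal(bel_average_precision(c(FALSE, FALSE)), 0)
  expect_equal(bel_average_precision(c(FALSE, TRUE)), 0.5)
})

test_that("MAP and bounds on two two-item lists match the closed form", {
  j <- mk_judgments(list(c(TRUE, FALSE), c(FALSE, TRUE)))
  s <- bel_map_with_bounds(j, "full", n_shuffles = 10, seed = 1)
  expect_equal(s$map, 0.75)       # (1.0 + 0.5) / 2
  expect_equal(s$map_best, 1.0)
  expect_equal(s$map_worst, 0.5)
  expect_equal(s$tp, 2L)
  expect_equal(s$fp, 2L)
  expect_equal(s$precision, 0.5)
})

test_that("degenerate all-relevant lists collapse all bounds to 1", {
  j <- mk_judgments(list(c(TRUE, TRUE, TRUE)))
  s <- bel_map_with_bounds(j, "full", n_shuffles = 5, seed = 1)
  expect_equal(c(s$map, s$map_worst, s$map_random, s$map_best), rep(1, 4))
})

test_that("relevance criteria are nested full < relaxed < context", {
  df <- data.frame(statement_id = "s1", rank = 1:4,
                   evidence_id = letters[1:4],
                   label = c("full", "relaxed", "context", "negative"),
                   sentence_count = 1L)
  class(df) <- c("bel_judgments", "data.frame")
  tps <- vapply(c("full", "relaxed", "context"), function(cr)
    bel_map_with_bounds(df, cr, n_shuffles = 2, seed = 1)$tp, integer(1))
  expect_equal(unname(tps), c(1L, 2L, 3L))
})

test_that("MAP with fixed seed is bit-reproducible and precision is rank-invariant", {
  j <- bel_sample_judgments(15, seed = 11)
  a <- bel_map_with_bounds(j, "relaxed", n_shuffles = 100, seed = 3)
  b <- bel_map_with_bounds(j, "relaxed", n_shuffles = 100, seed = 3)
  expect_identical(a, b)
  # permuting within statements changes MAP but never precision
  jr <- j[order(j$statement_id, -j$rank), ]
  jr$rank <- ave(jr$rank, jr$statement_id, FUN = seq_along)
  c1 <- bel_map_with_bounds(jr, "relaxed", n_shuffles = 100, seed = 3)
  expect_equal(c1$precision, a$precision)
  expect_equal(c1$tp, a$tp)
})

test_that("zero-relevant statements count AP = 0 unless excluded", {
  j <- mk_judgments(list(c(TRUE, TRUE), c(FALSE, FALSE)))
  inc <- bel_map_with_bounds(j, "full", n_shuffles = 2, seed = 1)
  exc <- bel_map_with_bounds(j, "full", n_shuffles = 2, seed = 1,
                             zero_relevant = "exclude")
  expect_equal(inc$map, 0.5)
  expect_equal(exc$map, 1.0)
  expect_equal(inc$n_statements, 2L)
  expect_equal(exc$n_statements, 1L)
})

test_that("judgment files load with length and size restrictions applied", {
  lines <- c(
    "# header comment",
    "s1\t1\te1\tfull\t1",
    "s1\t2\te2\tnegative\t2",
    "s1\t3\te3\trelaxed\t3",      # three sentences: discarded
    paste(sprintf("s2\t%d\te%d\tcontext\t1", 1:12, 100 + 1:12), collapse = "\n")
  )
  path <- withr::local_tempfile(lines = lines)
  expect_warning(expect_warning(j <- bel_read_judgments(path),
                                "longer than two sentences"),
                 "truncated to the top 10")
  expect_equal(nrow(j[j$statement_id == "s1", ]), 2L)
  expect_equal(nrow(j[j$statement_id == "s2", ]), 10L)

  bad <- withr::local_tempfile(lines = "s1\t1\te1\tmaybe\t1")
  expect_error(bel_read_judgments(bad), "unknown relevance label")
  short <- withr::local_tempfile(lines = "s1\t1\te1")
  expect_error(bel_read_judgments(short), "5 tab-separated columns")
})

test_that("random-bound MAP converges to the exact permutation mean", {
  set.seed(406)
  for (rep in 1:12) {
    n <- sample(3:6, 1)
    flags <- stats::runif(n) < 0.5
    if (!any(flags)) flags[1] <- TRUE
    if (all(flags)) flags[1] <- FALSE
    j <- mk_judgments(list(flags))
    s <- bel_map_with_bounds(j, "full", n_shuffles = 2000, seed = 1000 + rep)
    expect_lt(abs(s$map_random - exact_random_ap(flags)), 0.01)
  }
})
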