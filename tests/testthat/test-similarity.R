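mk_hits <- function(...) {
  m <- do.call(rbind, list(...))
  hits_table(m[, 1], m[, 2], as.numeric(m[, 3]))
}

test_that("relative reciprocal score follows the printed formula and clips", {
  expect_equal(relative_reciprocal_score(50, 50, 100, 100), 0.5)
  expect_equal(relative_reciprocal_score(80, 80, 80, 80), 1)
  # reciprocal scores above the self-scores clip to 1
  expect_equal(relative_reciprocal_score(120, 110, 100, 100), 1)
  expect_error(relative_reciprocal_score(10, 10, 0, 100), "positive")
})

test_that("similarity filters implement the absolute and reciprocal rules", {
  A <- g_str("A", "[x1 x2]")
  B <- g_str("B", "[y1 y2]")
  # relative filter: 70 < 0.8 * 100 removes the x1-y2 edge
  h <- mk_hits(c("x1", "y1", 100), c("y1", "x1", 100),
               c("x1", "y2", 70), c("y2", "x1", 70),
               c("x1", "x1", 100), c("y1", "y1", 100),
               c("y2", "y2", 100), c("x2", "x2", 100))
  S <- build_similarity_graph(A, B, h)
  expect_equal(nrow(S$edges), 1L)
  expect_equal(S$edges$a, "x1")
  expect_equal(S$edges$b, "y1")
  # absolute filter: sigma = 0.05 < 0.1 is discarded
  h2 <- mk_hits(c("x1", "y1", 5), c("y1", "x1", 5),
                c("x1", "x1", 100), c("y1", "y1", 100))
  S2 <- build_similarity_graph(A, B, h2)
  expect_equal(nrow(S2$edges), 0L)
  # mutually best reciprocal hits with sigma = 1: full planted matching
  h3 <- mk_hits(c("x1", "y1", 100), c("y1", "x1", 100),
                c("x2", "y2", 100), c("y2", "x2", 100),
                c("x1", "x1", 100), c("x2", "x2", 100),
                c("y1", "y1", 100), c("y2", "y2", 100))
  S3 <- build_similarity_graph(A, B, h3)
  expect_equal(nrow(S3$edges), 2L)
  expect_true(all(S3$edges$sigma == 1))
  expect_true(all(c(S3$w_a, S3$w_b) == 1))
})

test_that("vertex weights equal the maximum incident edge score", {
  A <- g_str("A", "[x1 x2 x3]")
  B <- g_str("B", "[y1 y2]")
  S <- sim_from(A, B, c("x1", "y1", 0.9), c("x1", "y2", 0.5),
                c("x2", "y2", 0.7))
  for (g in S$genes_a) {
    inc <- S$edges$sigma[S$edges$a == g]
    expect_equal(unname(S$w_a[g]), if (length(inc)) max(inc) else 0)
  }
  for (g in S$genes_b) {
    inc <- S$edges$sigma[S$edges$b == g]
    expect_equal(unname(S$w_b[g]), if (length(inc)) max(inc) else 0)
  }
  # isolated gene x3 stays a vertex with weight 0
  expect_equal(unname(S$w_a["x3"]), 0)
})

test_that("raising either threshold never adds an edge, and row order is
           irrelevant", {
  A <- g_str("A", "[x1 x2]")
  B <- g_str("B", "[y1 y2]")
  rows <- list(c("x1", "y1", 100), c("y1", "x1", 90),
               c("x1", "y2", 85), c("y2", "x1", 95),
               c("x2", "y2", 60), c("y2", "x2", 55),
               c("x1", "x1", 110), c("x2", "x2", 120),
               c("y1", "y1", 100), c("y2", "y2", 90))
  h <- do.call(mk_hits, rows)
  base <- build_similarity_graph(A, B, h, f_eps = 0.1, f_t = 0.5)
  key <- function(S) paste(S$edges$a, S$edges$b)
  for (fe in c(0.2, 0.5)) {
    for (ft in c(0.6, 0.9)) {
      S2 <- build_similarity_graph(A, B, h, f_eps = fe, f_t = ft)
      expect_true(all(key(S2) %in% key(base)))
    }
  }
  h_rev <- do.call(mk_hits, rev(rows))
  S_rev <- build_similarity_graph(A, B, h_rev, f_eps = 0.1, f_t = 0.5)
  expect_identical(S_rev$edges, base$edges)
})

test_that("missing self hits and unknown genes are handled", {
  A <- g_str("A", "[x1]")
  B <- g_str("B", "[y1]")
  h <- mk_hits(c("x1", "y1", 50), c("y1", "x1", 50), c("x1", "x1", 100))
  expect_error(build_similarity_graph(A, B, h), "missing self hit")
  h2 <- mk_hits(c("x1", "zz", 50), c("x1", "y1", 50), c("y1", "x1", 50),
                c("x1", "x1", 100), c("y1", "y1", 100))
  expect_warning(S <- build_similarity_graph(A, B, h2), "absent")
  expect_equal(nrow(S$edges), 1L)
})
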