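test_that("solver returns the forced solution on trivial instances", {
  A <- g_str("A", "[1 2]")
  B <- g_str("B", "[5 6]")
  S <- sim_from(A, B, c("1", "5", 1), c("2", "6", 1))
  sol <- solve_capped_ffr(optimal_capping(build_ffr(A, B, S)))
  expect_equal(sol$status, "optimal")
  expect_equal(nrow(sol$ortholog_set), 2L)
  expect_equal(sol$report$wd, 0)
  # all degrees <= 1: the single candidate matching is returned
  S2 <- sim_from(A, B, c("1", "5", 0.6))
  sol2 <- solve_capped_ffr(optimal_capping(build_ffr(A, B, S2)))
  expect_equal(sol2$ortholog_set$a, "1")
  expect_equal(sol2$status, "optimal")
})

test_that("exhaustive reference: empty graph and single-edge cases", {
  A <- g_str("A", "[1 2]")
  B <- g_str("B", "[5]")
  S0 <- sim_from(A, B)
  ffr0 <- build_ffr(A, B, S0)
  sol0 <- exhaustive_solve(optimal_capping(ffr0))
  expect_equal(nrow(sol0$ortholog_set), 0L)
  # wd = d + w(all genes); all weights are 0 here
  expect_equal(sol0$report$wd, sol0$report$d)
  # one similarity edge: min over take-it / leave-it
  S1 <- sim_from(A, B, c("1", "5", 0.9))
  ffr1 <- build_ffr(A, B, S1)
  sol1 <- exhaustive_solve(optimal_capping(ffr1))
  take <- weighted_distance(A, B, S1, cbind("1", "5"))$wd
  leave <- weighted_distance(A, B, S1, NULL)$wd
  expect_equal(sol1$report$wd, min(take, leave))
  expect_error(exhaustive_solve(optimal_capping(ffr1), max_edges = 0L),
               "guard")
})

test_that("branch-and-bound equals exhaustive enumeration on seeded
           instances", {
  for (s in 1:20) {
    inst <- random_ffr_instance(s)
    capped <- optimal_capping(inst$ffr)
    expect_equal(solve_capped_ffr(capped)$report$wd,
                 exhaustive_solve(capped)$report$wd,
                 info = paste("seed", s))
  }
})

test_that("worked-example ortholog-set ranking is respected by the
           optimum", {
  fx <- load_fixture("toy_pair")
  ffr <- build_ffr(fx$A, fx$B, fx$S)
  sol <- exhaustive_solve(optimal_capping(ffr), max_edges = 8L)
  # the optimum must be at least as good as the highlighted ortholog-set
  wd_highlighted <- weighted_distance(fx$A, fx$B, fx$S,
                                      fx$ortholog_set)$wd
  expect_lte(sol$report$wd, wd_highlighted)
  # and equals the minimum over every enumerated ortholog-set
  wds <- vapply(enumerate_ortholog_sets(ffr), function(O)
    weighted_distance(fx$A, fx$B, fx$S, O)$wd, numeric(1))
  expect_equal(sol$report$wd, min(wds))
})

test_that("cost preservation: optimal capping preserves the uncapped
           weighted cost for fixed sibling-sets", {
  # min over capping-sets of the capped cost == BFS-oracle based wd
  for (s in c(2, 3, 9, 12)) {
    inst <- random_ffr_instance(s, max_genes = 3, max_segments = 2,
                                edge_prob = 0.4)
    capped <- optimal_capping(inst$ffr)
    sets <- enumerate_ortholog_sets(inst$ffr)
    for (O in sets) {
      ev <- evaluate_capping(capped, O)
      d_true <- dcj_indel_distance_bfs(inst$A, inst$B, O,
                                       max_states = 4e5)
      expect_equal(ev$d, d_true, info = paste("seed", s))
    }
  }
})

test_that("heuristic capping never beats optimal capping, and matches it
           for single-segment genomes", {
  for (s in 1:12) {
    inst <- random_ffr_instance(s)
    wd_opt <- solve_capped_ffr(optimal_capping(inst$ffr))$report$wd
    C <- complete_to_perfect(
      build_shared_content_graph(inst$A, inst$B, inst$S))
    wd_heu <- solve_capped_ffr(
      heuristic_capping(inst$ffr, C))$report$wd
    expect_gte(wd_heu + 1e-9, wd_opt)
    if (kappa(inst$A) == 1L && kappa(inst$B) == 1L)
      expect_equal(wd_heu, wd_opt)
  }
})

test_that("pairwise driver is deterministic and composes the stages", {
  inst <- random_ffr_instance(4)
  hits <- NULL
  p1 <- gendiff_pair(inst$A, inst$B, S = inst$S, mode = "optimal")
  p2 <- gendiff_pair(inst$A, inst$B, S = inst$S, mode = "optimal")
  expect_identical(p1$solution$ortholog_set, p2$solution$ortholog_set)
  ph <- gendiff_pair(inst$A, inst$B, S = inst$S, mode = "heuristic")
  expect_gte(ph$solution$report$wd + 1e-9, p1$solution$report$wd)
  expect_s3_class(ph$content, "ffdcj_scg")
})

test_that("planted identical genomes solve to zero distance and full
           matching", {
  A <- g_str("A", "[1 2 3][4 5]")
  B <- g_str("B", "[11 12 13][14 15]")
  S <- sim_from(A, B, c("1", "11", 1), c("2", "12", 1), c("3", "13", 1),
                c("4", "14", 1), c("5", "15", 1))
  for (mode in c("optimal", "heuristic")) {
    p <- gendiff_pair(A, B, S = S, mode = mode)
    expect_equal(p$solution$report$wd, 0)
    expect_equal(nrow(p$solution$ortholog_set), 5L)
  }
})
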