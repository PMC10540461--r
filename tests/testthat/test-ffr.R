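test_that("relational graph of the worked example has the derived counts", {
  fx <- load_fixture("toy_pair")
  ffr <- build_ffr(fx$A, fx$B, fx$S)
  expect_equal(2L * (ffr$nA + ffr$nB), 26L)          # 13 genes
  expect_equal(ffr$nA + ffr$nB, 13L)                 # 6 + 7 indel edges
  n_adj_a <- sum(ffr$adj[seq_len(2L * ffr$nA)] > 0L) / 2L
  n_adj_b <- sum(ffr$adj[-seq_len(2L * ffr$nA)] > 0L) / 2L
  expect_equal(n_adj_a, 4)                           # segments of 4 and 2
  expect_equal(n_adj_b, 6)
  expect_equal(nrow(ffr$sim) * 2L, 2L * nrow(fx$S$edges))
})

test_that("degenerate relational graphs are well formed", {
  A <- g_str("A", "[x]")
  B <- g_str("B", "[y]")
  S <- sim_from(A, B, c("x", "y", 1))
  ffr <- build_ffr(A, B, S)
  expect_equal(2L * (ffr$nA + ffr$nB), 4L)
  expect_equal(nrow(ffr$sim), 1L)      # one sibling pair = 2 extremity edges
  expect_true(all(ffr$adj == 0L))      # no adjacency edges
  S0 <- sim_from(A, B)
  expect_equal(nrow(build_ffr(A, B, S0)$sim), 0L)
})

test_that("the worked-example decomposition has the published census", {
  fx <- load_fixture("toy_pair")
  ffr <- build_ffr(fx$A, fx$B, fx$S)
  dec <- induce_decomposition(ffr, fx$ortholog_set)
  expect_equal(dec$n_AB, 2L)
  expect_equal(dec$n_AA, 1L)
  expect_equal(dec$n_BB, 0L)
  expect_equal(dec$n_cycles, 1L)
})

test_that("identical single-segment genomes decompose as derived by hand", {
  A <- g_str("A", "[1 2]")
  B <- g_str("B", "[21 22]")
  S <- sim_from(A, B, c("1", "21", 1), c("2", "22", 1))
  dec <- induce_decomposition(build_ffr(A, B, S),
                              cbind(c("1", "2"), c("21", "22")))
  # hand enumeration: the two outer telomere pairs give two AB-paths,
  # the inner adjacencies close into one cycle
  expect_equal(dec$n_AB, 2L)
  expect_equal(dec$n_cycles, 1L)
  expect_equal(dec$n_AA + dec$n_BB, 0L)
})

test_that("path count always equals kappa(A) + kappa(B)", {
  for (s in 1:12) {
    inst <- random_ffr_instance(s)
    sets <- enumerate_ortholog_sets(inst$ffr)
    for (O in sets[seq_len(min(4, length(sets)))]) {
      dec <- induce_decomposition(inst$ffr, O)
      expect_equal(dec$n_AA + dec$n_BB + dec$n_AB,
                   kappa(inst$A) + kappa(inst$B))
    }
  }
})

test_that("empty ortholog-set still yields a full path census", {
  fx <- load_fixture("toy_pair")
  ffr <- build_ffr(fx$A, fx$B, fx$S)
  dec <- induce_decomposition(ffr, NULL)
  expect_equal(dec$n_AA + dec$n_BB + dec$n_AB, 3L)   # kappa 2 + 1
  expect_equal(dec$n_cycles, 0L)
})

test_that("invalid sibling-sets are rejected", {
  fx <- load_fixture("toy_pair")
  ffr <- build_ffr(fx$A, fx$B, fx$S)
  expect_error(induce_decomposition(ffr, cbind(c("2", "4"), c("9", "9"))),
               "matching")
  expect_error(induce_decomposition(ffr, cbind("1", "13")),
               "not present")
})

test_that("weighted distance assembles its four terms", {
  # direct evaluation of the formula on a computed report
  A <- g_str("A", "[1 2]")
  B <- g_str("B", "[21 22]")
  S <- sim_from(A, B, c("1", "21", 1), c("2", "22", 1))
  r <- weighted_distance(A, B, S, cbind(c("1", "2"), c("21", "22")))
  expect_equal(r$d, 0L)
  expect_equal(r$wd, 0)          # every term cancels on identical genomes
  # empty matching: wd = d + w(all genes)
  r0 <- weighted_distance(A, B, S, NULL)
  expect_equal(r0$o_size, 0L)
  expect_equal(r0$wd, r0$d + sum(S$w_a) + sum(S$w_b))
  expect_true(r0$wd >= r0$d)
  # arbitrary report respects wd = d + |O| - sigma(O) + w(complement)
  S2 <- sim_from(A, B, c("1", "21", 0.5), c("2", "22", 0.8))
  r2 <- weighted_distance(A, B, S2, cbind("1", "21"))
  expect_equal(r2$wd, r2$d + r2$o_size - r2$sigma_o + r2$w_comp)
  expect_equal(r2$sigma_o, 0.5)
  expect_equal(r2$w_comp, 1.6)  # genes 2 and 22 both unmatched, w = 0.8
})

test_that("wd is invariant under gene relabeling and segment reversal", {
  inst <- random_ffr_instance(5)
  sets <- enumerate_ortholog_sets(inst$ffr)
  O <- sets[[which.max(vapply(sets, nrow, integer(1)))]]
  wd0 <- weighted_distance(inst$A, inst$B, inst$S, O)$wd
  # relabel genes of A
  map <- stats::setNames(paste0("z", seq_along(inst$S$genes_a)),
                         inst$S$genes_a)
  A2 <- genome("A2", lapply(inst$A$segments, function(s)
    list(genes = unname(map[s$genes]), orient = s$orient)))
  S2 <- similarity_graph(A2, inst$B,
                         data.frame(a = unname(map[inst$S$edges$a]),
                                    b = inst$S$edges$b,
                                    sigma = inst$S$edges$sigma))
  O2 <- O; O2$a <- unname(map[O$a])
  expect_equal(weighted_distance(A2, inst$B, S2, O2)$wd, wd0)
  # reverse a whole segment of B
  segs <- inst$B$segments
  segs[[1]] <- list(genes = rev(segs[[1]]$genes),
                    orient = -rev(segs[[1]]$orient))
  B2 <- genome("B2", segs)
  S3 <- similarity_graph(inst$A, B2, inst$S$edges)
  expect_equal(weighted_distance(inst$A, B2, S3, O)$wd, wd0)
})

test_that("distance matches the search oracle on the worked mutation
           examples", {
  tp <- load_fixture("translocation_pair")
  expect_equal(dcj_indel_distance(tp$A, tp$B, tp$matching), 1L)
  expect_equal(dcj_indel_distance_bfs(tp$A, tp$B, tp$matching), 1L)
  dp <- load_fixture("deletion_pair")
  expect_equal(dcj_indel_distance(dp$A, dp$B, dp$matching), 1L)
  expect_equal(dcj_indel_distance_bfs(dp$A, dp$B, dp$matching), 1L)
  A <- g_str("A", "[1 2][3]")
  ident <- cbind(c("1", "2", "3"), c("1", "2", "3"))
  B <- genome("B", A$segments)
  expect_equal(dcj_indel_distance(A, B, ident), 0L)
  expect_equal(dcj_indel_distance_bfs(A, B, ident), 0L)
})

test_that("capped distance equals the state-space oracle on random tiny
           instances", {
  checked <- 0L
  for (s in 1:14) {
    inst <- random_ffr_instance(s, max_genes = 3, max_segments = 2,
                                edge_prob = 0.5)
    sets <- enumerate_ortholog_sets(inst$ffr)
    sets <- sets[order(-vapply(sets, nrow, integer(1)))]
    for (O in sets[seq_len(min(2, length(sets)))]) {
      d_formula <- dcj_indel_distance(inst$A, inst$B, O)
      d_oracle <- dcj_indel_distance_bfs(inst$A, inst$B, O,
                                         max_states = 4e5)
      expect_equal(d_formula, d_oracle,
                   info = paste("seed", s, "O size", nrow(O)))
      checked <- checked + 1L
    }
  }
  expect_gte(checked, 20L)
})
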