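test_that("optimal capping sizes follow the printed formulas", {
  fx <- load_fixture("toy_pair")            # kappa 2 and 1
  cap <- optimal_capping(build_ffr(fx$A, fx$B, fx$S))
  expect_equal(cap$p, 2L)
  expect_equal(cap$n_cap_edges, 16L)        # (2p)^2
  expect_equal(cap$n_capping_sets, 24)      # (2p)!
  expect_equal(sum(cap$tel_cap_b == 0L), 2L)  # one dummy adjacency in B
  A <- g_str("A", "[1]")
  B <- g_str("B", "[2]")
  cap1 <- optimal_capping(build_ffr(A, B, sim_from(A, B)))
  expect_equal(cap1$n_cap_edges, 4L)
  expect_equal(sum(cap1$tel_cap_a == 0L) + sum(cap1$tel_cap_b == 0L), 0L)
  # kappa = 507 on both sides
  expect_equal((2L * 507L)^2, 1028196L)
})

test_that("shared-content scores sum the similarity scores per segment
           pair", {
  A <- g_str("A", "[x1 x2][x3]")
  B <- g_str("B", "[y1][y2]")
  S <- sim_from(A, B, c("x1", "y1", 0.9), c("x2", "y1", 0.5),
                c("x3", "y2", 0.4))
  C <- build_shared_content_graph(A, B, S, tau = 5, eps = 0.01)
  e1 <- C$edges[C$edges$a == "seg1" & C$edges$b == "seg1", ]
  expect_equal(e1$omega, 1.4)
  expect_equal(nrow(C$edges), 2L)
})

test_that("tau filter keeps an edge only within the top ranks of both
           endpoints", {
  # hand enumeration: vertex with scores (1, 0.5, 0.1), tau = 2, partners
  # of degree one -> the weakest edge fails the centre vertex's top-2
  A <- g_str("A", "[x1]")
  B <- g_str("B", "[y1][y2][y3]")
  S <- sim_from(A, B, c("x1", "y1", 1), c("x1", "y2", 0.5),
                c("x1", "y3", 0.1))
  C <- build_shared_content_graph(A, B, S, tau = 2, eps = 0.01)
  expect_equal(nrow(C$edges), 2L)
  expect_false(any(C$edges$b == "seg3"))
  # ties at rank tau are all kept
  S2 <- sim_from(A, B, c("x1", "y1", 1), c("x1", "y2", 0.5),
                 c("x1", "y3", 0.5))
  C2 <- build_shared_content_graph(A, B, S2, tau = 2, eps = 0.01)
  expect_equal(nrow(C2$edges), 3L)
})

test_that("eps filter removes edges weak relative to their endpoints", {
  A <- g_str("A", "[x1][x2]")
  B <- g_str("B", "[y1 y2 y3]")
  # surviving scores at segment y-side vertex: 1.0 and 0.09 -> removed
  S <- sim_from(A, B, c("x1", "y1", 1), c("x2", "y2", 0.09))
  # both x segments connect to the same B segment
  C <- build_shared_content_graph(A, B, S, tau = 3, eps = 0.1)
  expect_equal(nrow(C$edges), 1L)
  expect_equal(C$edges$a, "seg1")
  # a score above eps * max survives
  S2 <- sim_from(A, B, c("x1", "y1", 1), c("x2", "y2", 0.11))
  C2 <- build_shared_content_graph(A, B, S2, tau = 3, eps = 0.1)
  expect_equal(nrow(C2$edges), 2L)
})

test_that("Hall violators follow alternating reachability", {
  # star: three left segments all adjacent to one right segment
  C <- scg_from(paste0("A", 1:3), "B1",
                data.frame(a = paste0("A", 1:3), b = "B1",
                           omega = c(3, 2, 1)))
  M <- ffdcj:::scg_max_matching(C)
  expect_equal(nrow(M), 1L)
  v <- setdiff(paste0("A", 1:3), M$a)[1]
  S <- find_hall_violator(C, M, v)
  expect_setequal(S, c(v, M$a))
  expect_lt(length(ffdcj:::scg_neighbourhood(C, S, "a")), length(S))
  expect_error(find_hall_violator(C, M, M$a[1]), "saturated")
})

test_that("completion adds the expected dummies on the worked example and
           prunes non-matchable edges", {
  C <- load_fixture("segment_graph")
  Ch <- complete_to_perfect(C)
  expect_equal(length(Ch$dummy_a), 1L)
  expect_equal(length(Ch$dummy_b), 1L)
  # the A3-B1 edge is non-matchable and got removed
  expect_false(any(Ch$edges$a == "A3" & Ch$edges$b == "B1"))
  # the component {A1,A2,A3 | B1,B2,dummy} is not complete bipartite
  comp_edges <- Ch$edges[Ch$edges$a %in% c("A1", "A2", "A3"), ]
  expect_lt(nrow(comp_edges), 9L)
  # every remaining edge lies in some perfect matching (brute force)
  adj <- ffdcj:::scg_biadjacency(Ch)
  pms <- all_perfect_matchings(adj)
  expect_gt(length(pms), 0L)
  sides <- ffdcj:::scg_sides(Ch)
  for (k in seq_len(nrow(Ch$edges))) {
    i <- match(Ch$edges$a[k], sides$a)
    j <- match(Ch$edges$b[k], sides$b)
    expect_true(any(vapply(pms, function(pm) pm[i] == j, logical(1))))
  }
})

test_that("graphs that already admit a perfect matching only get pruned", {
  C <- scg_from(c("A1", "A2"), c("B1", "B2"),
                data.frame(a = c("A1", "A1", "A2"),
                           b = c("B1", "B2", "B2"),
                           omega = c(1, 1, 1)))
  Ch <- complete_to_perfect(C)
  expect_length(Ch$dummy_a, 0L)
  expect_length(Ch$dummy_b, 0L)
  # A1-B2 would leave B1 unmatchable: pruned
  expect_equal(nrow(Ch$edges), 2L)
  # two left segments sharing one right segment get one dummy
  C2 <- scg_from(c("A1", "A2"), "B1",
                 data.frame(a = c("A1", "A2"), b = c("B1", "B1"),
                            omega = c(1, 1)))
  Ch2 <- complete_to_perfect(C2)
  expect_length(Ch2$dummy_b, 1L)
  expect_equal(sum(Ch2$edges$b == Ch2$dummy_b), 2L)
})

test_that("pruning equals the brute-force matchable-edge set on random
           bipartite graphs", {
  set.seed(42)
  for (rep in 1:40) {
    n <- sample(2:5, 1)
    adj <- matrix(runif(n * n) < 0.5, n, n)
    pms <- all_perfect_matchings(adj)
    if (!length(pms)) next
    edges <- which(adj, arr.ind = TRUE)
    C <- scg_from(paste0("A", 1:n), paste0("B", 1:n),
                  data.frame(a = paste0("A", edges[, 1]),
                             b = paste0("B", edges[, 2]),
                             omega = 1))
    Cp <- prune_non_matchable(C)
    for (k in seq_len(nrow(edges))) {
      i <- edges[k, 1]; j <- edges[k, 2]
      in_some_pm <- any(vapply(pms, function(pm) pm[i] == j, logical(1)))
      kept <- any(Cp$edges$a == paste0("A", i) &
                    Cp$edges$b == paste0("B", j))
      expect_equal(kept, in_some_pm, info = paste("rep", rep, i, j))
    }
  }
})

test_that("heuristic cap edges follow the crosswise rule and the dummy
           optimisation", {
  # single real-real edge: 4 cap edges
  A <- g_str("A", "[1 2]")
  B <- g_str("B", "[5 6]")
  S <- sim_from(A, B, c("1", "5", 1), c("2", "6", 1))
  C <- complete_to_perfect(build_shared_content_graph(A, B, S))
  cap <- heuristic_capping(build_ffr(A, B, S), C)
  expect_equal(cap$n_cap_edges, 4L)
  # dummy in a larger component keeps all 4 crosswise cap edges per edge
  A2 <- g_str("A", "[1][2]")
  B2 <- g_str("B", "[5 6]")
  S2 <- sim_from(A2, B2, c("1", "5", 1), c("2", "6", 1))
  C2 <- complete_to_perfect(build_shared_content_graph(A2, B2, S2))
  expect_length(C2$dummy_b, 1L)
  cap2 <- heuristic_capping(build_ffr(A2, B2, S2), C2)
  expect_equal(cap2$n_cap_edges, 4L * nrow(C2$edges))
  # heuristic never exceeds the optimal cap-edge count
  expect_lte(cap2$n_cap_edges,
             optimal_capping(build_ffr(A2, B2, S2))$n_cap_edges)
  # single-edge component with a dummy endpoint: one crosswise pairing only
  A3 <- g_str("A", "[1][2]")
  B3 <- g_str("B", "[5]")
  S3 <- sim_from(A3, B3, c("1", "5", 1))
  C3 <- complete_to_perfect(build_shared_content_graph(A3, B3, S3))
  expect_length(C3$dummy_b, 1L)
  cap3 <- heuristic_capping(build_ffr(A3, B3, S3), C3)
  expect_equal(cap3$n_cap_edges, 6L)   # 4 (real pair) + 2 (dummy pair)
})

test_that("capping-set existence matches perfect-matching existence
           (both directions, exhaustive on small graphs)", {
  check_graph <- function(n, mask) {
    adj <- matrix(bitwAnd(mask, 2L^(seq_len(n * n) - 1L)) > 0, n, n)
    edges <- which(adj, arr.ind = TRUE)
    if (!nrow(edges)) return(invisible(NULL))
    C <- scg_from(paste0("A", 1:n), paste0("B", 1:n),
                  data.frame(a = paste0("A", edges[, 1]),
                             b = paste0("B", edges[, 2]), omega = 1))
    has_pm <- length(all_perfect_matchings(adj)) > 0
    capmat <- ffdcj:::cap_matrix_from_scg(C)
    cap_pm <- ffdcj:::bip_max_matching_cpp(capmat)$size == 2L * n
    expect_equal(cap_pm, has_pm, info = paste("n", n, "mask", mask))
    invisible(NULL)
  }
  for (n in 1:3)
    for (mask in seq_len(2L^(n * n) - 1L)) check_graph(n, mask)
  # size 4: random sample of masks plus the full graph
  set.seed(7)
  for (mask in c(2L^16L - 1L, sample.int(2L^16L - 1L, 300L)))
    check_graph(4L, mask)
})

test_that("search-space bounds are tight on complete graphs and count
           matchings exactly on small ones", {
  k22 <- scg_from(c("A1", "A2"), c("B1", "B2"),
                  expand.grid(a = c("A1", "A2"), b = c("B1", "B2"),
                              omega = 1, stringsAsFactors = FALSE))
  b <- capping_search_space_bound(k22)
  expect_equal(b$bound, 2, tolerance = 1e-9)
  expect_equal(b$exact, 2)
  k33 <- scg_from(paste0("A", 1:3), paste0("B", 1:3),
                  expand.grid(a = paste0("A", 1:3), b = paste0("B", 1:3),
                              omega = 1, stringsAsFactors = FALSE))
  b3 <- capping_search_space_bound(k33)
  expect_equal(b3$bound, 6, tolerance = 1e-9)
  expect_equal(b3$exact, 6)
  diag3 <- scg_from(paste0("A", 1:3), paste0("B", 1:3),
                    data.frame(a = paste0("A", 1:3), b = paste0("B", 1:3),
                               omega = 1))
  bd <- capping_search_space_bound(diag3)
  expect_equal(bd$bound, 1, tolerance = 1e-9)
  expect_equal(bd$exact, 1)
})

test_that("segments in different content components never share cap
           edges", {
  A <- g_str("A", "[1 2][3]")
  B <- g_str("B", "[5 6][7]")
  S <- sim_from(A, B, c("1", "5", 1), c("2", "6", 0.9), c("3", "7", 1))
  C <- complete_to_perfect(build_shared_content_graph(A, B, S))
  cap <- heuristic_capping(build_ffr(A, B, S), C)
  # caps 1:2 belong to segment 1 of A, caps 3:4 to segment 2, same for B;
  # the two components must occupy disjoint blocks
  expect_true(all(!cap$allowed[1:2, 3:4]))
  expect_true(all(!cap$allowed[3:4, 1:2]))
})
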