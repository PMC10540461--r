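pair_df <- function(ga, gb, a, b, sigma = 0.9) {
  data.frame(gene_a = a, genome_a = ga, gene_b = b, genome_b = gb,
             sigma = sigma, stringsAsFactors = FALSE)
}

test_that("integration takes connected components as families", {
  fg <- integrate_ortholog_sets(list(
    pair_df("A", "B", "a1", "b1"),
    pair_df("B", "C", "b1", "c1")))
  cls <- classify_families(fg, n = 3)
  expect_length(cls$families, 1L)
  expect_setequal(cls$families[[1]]$genes, c("a1", "b1", "c1"))
  fg2 <- integrate_ortholog_sets(list(
    pair_df("A", "B", c("a1", "a2"), c("b1", "b2"))))
  expect_length(classify_families(fg2, n = 2)$families, 2L)
  expect_error(integrate_ortholog_sets(list(
    pair_df("A", "B", c("a1", "a2"), c("b1", "b1")))), "matching")
  expect_error(integrate_ortholog_sets(list(
    pair_df("A", "A", "a1", "a2"))), "within-genome")
})

test_that("family classes follow the one-gene-per-genome taxonomy", {
  # a3 and a4 (both genome A) join one component through genes of B and C
  fg <- integrate_ortholog_sets(list(
    pair_df("A", "B", c("a1", "a2", "a3"), c("b1", "b2", "b3")),
    pair_df("A", "C", c("a3", "a4"), c("c3", "c3b")),
    pair_df("B", "C", c("b1", "b3"), c("c1", "c3b"))))
  cls <- classify_families(fg, n = 3)
  byg <- function(genes) {
    f <- Filter(function(x) setequal(x$genes, genes), cls$families)
    if (length(f)) f[[1]]$class else NA_character_
  }
  expect_equal(byg(c("a1", "b1", "c1")), "resolved-complete")
  expect_equal(byg(c("a2", "b2")), "resolved-incomplete")
  # a3 and a4 are both genome-A genes connected through c3/b3/c3b
  amb <- Filter(function(x) x$class == "ambiguous", cls$families)
  expect_length(amb, 1L)
  expect_true(all(c("a3", "a4") %in% amb[[1]]$genes))
})

test_that("markov clustering splits weakly bridged cliques and respects
           symmetry", {
  genes <- c(paste0("x", 1:3), paste0("y", 1:3))
  adj <- matrix(0, 6, 6, dimnames = list(genes, genes))
  adj[1:3, 1:3] <- 1; adj[4:6, 4:6] <- 1
  diag(adj) <- 0
  adj["x1", "y1"] <- adj["y1", "x1"] <- 0.01
  cl <- mcl_cluster(adj)
  expect_length(cl, 2L)
  expect_setequal(cl[[which(vapply(cl, function(x) "x1" %in% x,
                                   logical(1)))]], paste0("x", 1:3))
  # uniform clique: one cluster (symmetry)
  k4 <- matrix(1, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  diag(k4) <- 0
  expect_length(mcl_cluster(k4), 1L)
  # single-edge family: nothing to split
  e2 <- matrix(c(0, 1, 1, 0), 2, 2, dimnames = list(c("a", "b"),
                                                    c("a", "b")))
  expect_length(mcl_cluster(e2), 1L)
})

test_that("refinement conserves genes and only removes pairs", {
  # two triplets joined by one weak cross pair (b1-c2): ambiguous component
  fg <- integrate_ortholog_sets(list(
    pair_df("A", "B", c("a1", "a2"), c("b1", "b2"), sigma = c(1, 1)),
    pair_df("A", "C", c("a1", "a2"), c("c1", "c2"), sigma = c(1, 1)),
    pair_df("B", "C", c("b1", "b2"), c("c2", "c1"),
            sigma = c(0.02, 0.02))))
  cls <- classify_families(fg, n = 3)
  amb <- Filter(function(x) x$class == "ambiguous", cls$families)
  expect_length(amb, 1L)
  refined <- refine_families(cls, fg)
  genes_before <- sort(unlist(lapply(cls$families, `[[`, "genes")))
  genes_after <- sort(c(unlist(lapply(refined$families, `[[`, "genes")),
                        refined$unclassified))
  expect_equal(genes_after, sort(c(genes_before, cls$unclassified)))
  # refined pair sets shrink
  pk <- function(fams) {
    fs <- lapply(fams$families, `[[`, "genes")
    unlist(lapply(fs, function(f)
      if (length(f) > 1) apply(utils::combn(sort(f), 2), 2, paste,
                               collapse = "|") else character(0)))
  }
  expect_true(all(pk(refined) %in% pk(cls)))
  # non-ambiguous input is returned unchanged with a warning
  fam_ok <- list(genes = c("a9", "b9"), class = "resolved-incomplete")
  expect_warning(out <- mcl_refine(fam_ok, fg$edges, 3,
                                   c(a9 = "A", b9 = "B")), "not ambiguous")
  expect_identical(out[[1]], fam_ok)
})

test_that("pair metrics match the hand-enumerated example and its
           identities", {
  X <- family_set(list(c("a1", "b1"), c("a2", "b2", "c2")))
  ref <- family_set(list(c("a1", "b1", "c1"), c("a2", "b2"), "c2"))
  m <- homology_pair_metrics(X, ref)
  expect_equal(c(m$tp, m$fp, m$fn), c(2L, 2L, 2L))
  expect_equal(m$precision, 0.5)
  expect_equal(m$recall, 0.5)
  # X = ref
  mi <- homology_pair_metrics(ref, ref)
  expect_equal(c(mi$precision, mi$recall, mi$f1), c(1, 1, 1))
  # all singletons: degenerate, zero by convention
  ms <- homology_pair_metrics(family_set(list("a1", "b1")), ref)
  expect_true(ms$degenerate)
  expect_equal(ms$precision, 0)
  # swapping X and ref swaps precision and recall (same gene universe)
  X2 <- family_set(list(c("a1", "b1"), c("a2", "b2"), c("c1", "c2")))
  m12 <- homology_pair_metrics(X2, ref)
  m21 <- homology_pair_metrics(ref, X2)
  expect_equal(m12$precision, m21$recall)
  expect_equal(m12$recall, m21$precision)
})
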