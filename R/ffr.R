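# Family-free relational graph: gene extremities, adjacency/extremity/indel
# edges, consistent decompositions and the DCJ-indel cost machinery.
#
# Extremity encoding: genes of each genome are numbered 1..n in segment
# order; tail(g) = 2g-1, head(g) = 2g.  Extremities of genome B are offset
# by 2*nA in the global vertex numbering.  The left end of a forward gene is
# its tail, of a reverse gene its head.

ext_tail <- function(g) 2L * g - 1L
ext_head <- function(g) 2L * g

#' Build the family-free relational graph of two genomes
#'
#' Vertices are the head/tail extremities of every gene of `A` and `B`.
#' Adjacency edges connect consecutive gene extremities within each linear
#' segment; every similarity edge ab contributes the sibling pair of
#' extremity edges a^t b^t and a^h b^h (equal scores); every gene
#' contributes one indel edge between its two extremities, weighted by the
#' gene's vertex weight in the similarity graph.
#'
#' @param A,B `ffdcj_genome` objects.
#' @param S An `ffdcj_simgraph` over `A` and `B` (see
#'   [build_similarity_graph()] / [similarity_graph()]).
#' @return An object of class `ffdcj_ffr`.
#' @export
build_ffr <- function(A, B, S) {
  stopifnot(inherits(A, "ffdcj_genome"), inherits(B, "ffdcj_genome"),
            inherits(S, "ffdcj_simgraph"))
  ta <- gene_table(A)
  tb <- gene_table(B)
  if (!identical(ta$gene, S$genes_a) || !identical(tb$gene, S$genes_b))
    stop("similarity graph does not match the genomes")
  nA <- nrow(ta)
  nB <- nrow(tb)
  side_layout <- function(tab, offset) {
    n <- nrow(tab)
    left <- ifelse(tab$orient > 0L, ext_tail(seq_len(n)), ext_head(seq_len(n)))
    right <- ifelse(tab$orient > 0L, ext_head(seq_len(n)), ext_tail(seq_len(n)))
    adj <- integer(2L * n)  # adjacency partner per extremity, 0 = telomere
    telomeres <- integer(0)
    for (sid in unique(tab$segment)) {
      gi <- which(tab$segment == sid)
      if (length(gi) > 1L) {
        for (k in seq_len(length(gi) - 1L)) {
          u <- right[gi[k]]
          v <- left[gi[k + 1L]]
          adj[u] <- v
          adj[v] <- u
        }
      }
      telomeres <- c(telomeres, left[gi[1L]], right[gi[length(gi)]])
    }
    list(adj = adj + ifelse(adj > 0L, offset, 0L),
         telomeres = telomeres + offset)
  }
  la <- side_layout(ta, 0L)
  lb <- side_layout(tb, 2L * nA)
  ai <- match(S$edges$a, ta$gene)
  bi <- match(S$edges$b, tb$gene)
  structure(list(
    A = A, B = B, S = S, nA = nA, nB = nB,
    gene_a = ta$gene, gene_b = tb$gene,
    adj = c(la$adj, lb$adj),
    telomeres_a = la$telomeres, telomeres_b = lb$telomeres,
    sim = data.frame(ai = ai, bi = bi, sigma = S$edges$sigma),
    w_a = as.numeric(S$w_a[ta$gene]), w_b = as.numeric(S$w_b[tb$gene])
  ), class = "ffdcj_ffr")
}

#' @export
print.ffdcj_ffr <- function(x, ...) {
  n_adj_a <- sum(x$adj[seq_len(2L * x$nA)] > 0L) / 2L
  n_adj_b <- sum(x$adj[-seq_len(2L * x$nA)] > 0L) / 2L
  cat("Family-free relational graph: ", 2L * (x$nA + x$nB), " vertices\n",
      "  adjacency edges: ", n_adj_a, " + ", n_adj_b, "\n",
      "  extremity edges: ", 2L * nrow(x$sim), " (", nrow(x$sim),
      " sibling pairs)\n",
      "  indel edges:     ", x$nA, " + ", x$nB, "\n", sep = "")
  invisible(x)
}

# Normalise an ortholog-set argument into a two-column character matrix.
as_ortholog_pairs <- function(O) {
  if (is.null(O) || (is.data.frame(O) && nrow(O) == 0L) ||
      (is.matrix(O) && nrow(O) == 0L) || (is.list(O) && length(O) == 0L))
    return(matrix(character(0), ncol = 2))
  if (is.data.frame(O)) {
    cols <- intersect(c("a", "b"), names(O))
    if (length(cols) < 2L) cols <- intersect(c("gene_a", "gene_b"), names(O))
    if (length(cols) < 2L) cols <- names(O)[1:2]
    m <- cbind(as.character(O[[cols[1]]]), as.character(O[[cols[2]]]))
  } else if (is.matrix(O)) {
    m <- cbind(as.character(O[, 1]), as.character(O[, 2]))
  } else if (is.list(O)) {
    m <- do.call(rbind, lapply(O, function(p) as.character(p[1:2])))
  } else stop("cannot interpret ortholog-set")
  m
}

# Map an ortholog-set to similarity-edge indices of an ffr; validates that
# every pair is an edge of S and that the set is a matching.
ortholog_set_to_L <- function(ffr, O) {
  m <- as_ortholog_pairs(O)
  if (nrow(m) == 0L) return(integer(0))
  key_edges <- paste(ffr$gene_a[ffr$sim$ai], ffr$gene_b[ffr$sim$bi],
                     sep = "\r")
  # accept pairs in either order
  k1 <- paste(m[, 1], m[, 2], sep = "\r")
  k2 <- paste(m[, 2], m[, 1], sep = "\r")
  idx <- match(k1, key_edges)
  idx[is.na(idx)] <- match(k2, key_edges)[is.na(idx)]
  if (anyNA(idx))
    stop("ortholog pair(s) not present as similarity edges: ",
         paste(k1[is.na(idx)], collapse = ", "))
  check_sibling_set(ffr, idx)
  idx
}

check_sibling_set <- function(ffr, L) {
  if (anyDuplicated(L)) stop("duplicate edges in sibling-set")
  if (anyDuplicated(ffr$sim$ai[L]) || anyDuplicated(ffr$sim$bi[L]))
    stop("sibling-set has incident edges (not a matching)")
  invisible(TRUE)
}

# Decompose the FFR under a sibling-set L (vector of similarity-edge
# indices).  Returns paths (with ends and ordered indel-run labels),
# cycles (cyclic label sequences) and a component census.
decompose_ffr <- function(ffr, L) {
  nA <- ffr$nA
  nB <- ffr$nB
  nV <- 2L * (nA + nB)
  gene_partner <- integer(nV)
  indel_label <- integer(nV)  # label recorded when leaving via gene edge
  # default: indel edges (head <-> tail of the same gene)
  for (g in seq_len(nA)) {
    gene_partner[ext_tail(g)] <- ext_head(g)
    gene_partner[ext_head(g)] <- ext_tail(g)
    indel_label[c(ext_tail(g), ext_head(g))] <- 1L
  }
  off <- 2L * nA
  for (g in seq_len(nB)) {
    gene_partner[off + ext_tail(g)] <- off + ext_head(g)
    gene_partner[off + ext_head(g)] <- off + ext_tail(g)
    indel_label[off + c(ext_tail(g), ext_head(g))] <- 2L
  }
  # matched genes: extremity (sibling) edges replace indel edges
  for (e in L) {
    ga <- ffr$sim$ai[e]
    gb <- ffr$sim$bi[e]
    at <- ext_tail(ga); ah <- ext_head(ga)
    bt <- off + ext_tail(gb); bh <- off + ext_head(gb)
    gene_partner[at] <- bt; gene_partner[bt] <- at
    gene_partner[ah] <- bh; gene_partner[bh] <- ah
    indel_label[c(at, ah, bt, bh)] <- 0L
  }
  adj <- ffr$adj
  visited <- logical(nV)
  side_of <- function(v) if (v <= 2L * nA) "A" else "B"
  paths <- list()
  for (t in c(ffr$telomeres_a, ffr$telomeres_b)) {
    if (visited[t]) next
    runs <- integer(0)
    len <- 0L
    cur <- t
    repeat {
      g <- gene_partner[cur]
      if (indel_label[cur] > 0L) runs <- c(runs, indel_label[cur])
      visited[cur] <- TRUE
      visited[g] <- TRUE
      len <- len + 1L
      nxt <- adj[g]
      if (nxt == 0L) { end2 <- g; break }
      cur <- nxt
      len <- len + 1L
    }
    type <- paste0(sort(c(side_of(t), side_of(end2))), collapse = "")
    paths[[length(paths) + 1L]] <-
      list(end1 = t, end2 = end2, runs = runs, type = type, length = len)
  }
  cycles <- list()
  for (v in seq_len(nV)) {
    if (visited[v]) next
    runs <- integer(0)
    len <- 0L
    cur <- v
    repeat {
      g <- gene_partner[cur]
      if (indel_label[cur] > 0L) runs <- c(runs, indel_label[cur])
      visited[cur] <- TRUE
      visited[g] <- TRUE
      len <- len + 2L
      cur <- adj[g]
      if (cur == v) break
    }
    cycles[[length(cycles) + 1L]] <- list(runs = runs, length = len)
  }
  list(paths = paths, cycles = cycles)
}

#' Induce the consistent decomposition of a sibling-set
#'
#' Given an ortholog-set (equivalently its sibling-set), computes the
#' decomposition of the relational graph into vertex-disjoint cycles and
#' paths: the sibling edges, the indel edges of unmatched genes and all
#' adjacency edges.  Paths end at telomeres and are typed AA, BB or AB by
#' the genomes of their two ends.
#'
#' @param ffr An `ffdcj_ffr`.
#' @param O Ortholog-set: data.frame/matrix of gene-id pairs (genes of A
#'   first), each of which must be a similarity edge; must be a matching.
#' @return An object of class `ffdcj_decomposition` with the component
#'   census (`n_cycles`, `n_AA`, `n_BB`, `n_AB`) and the components.
#' @export
induce_decomposition <- function(ffr, O) {
  stopifnot(inherits(ffr, "ffdcj_ffr"))
  L <- ortholog_set_to_L(ffr, O)
  dec <- decompose_ffr(ffr, L)
  types <- vapply(dec$paths, `[[`, character(1), "type")
  structure(list(
    L = L, paths = dec$paths, cycles = dec$cycles,
    n_cycles = length(dec$cycles),
    n_AA = sum(types == "AA"), n_BB = sum(types == "BB"),
    n_AB = sum(types == "AB"),
    census = data.frame(
      type = c(rep("cycle", length(dec$cycles)), types),
      length = c(vapply(dec$cycles, `[[`, integer(1), "length"),
                 vapply(dec$paths, `[[`, integer(1), "length")))
  ), class = "ffdcj_decomposition")
}

#' @export
print.ffdcj_decomposition <- function(x, ...) {
  cat("Consistent decomposition: ", x$n_cycles, " cycle(s), ",
      x$n_AB, " AB-path(s), ", x$n_AA, " AA-path(s), ",
      x$n_BB, " BB-path(s)\n", sep = "")
  invisible(x)
}

#' Write a decomposition census as TSV
#' @param dec An `ffdcj_decomposition`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_census <- function(dec, path) {
  stopifnot(inherits(dec, "ffdcj_decomposition"))
  utils::write.table(dec$census, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# Evaluate the minimum DCJ-indel operation count of a capped decomposition,
# minimising over all capping-sets allowed by the capped graph.
# Returns list(valid, d, n_capping_sets, n_optimal, max_paths_single_cycle,
# best_matching).
eval_capped_L <- function(capped, L, max_enum = 1e7) {
  ffr <- capped$ffr
  dec <- decompose_ffr(ffr, L)
  base <- 0L
  for (cy in dec$cycles)
    base <- base + cycle_run_cost_cpp(cy$runs) - 1L
  p2 <- 2L * capped$p
  # path objects: real paths first, then dummy adjacencies
  npaths <- length(dec$paths)
  path_runs <- lapply(dec$paths, `[[`, "runs")
  path_real <- rep(TRUE, npaths)
  cap_path_a <- integer(p2); cap_slot_a <- integer(p2)
  cap_path_b <- integer(p2); cap_slot_b <- integer(p2)
  # map telomere vertex -> (path, slot)
  if (npaths) {
    e1 <- vapply(dec$paths, `[[`, integer(1), "end1")
    e2 <- vapply(dec$paths, `[[`, integer(1), "end2")
  } else e1 <- e2 <- integer(0)
  locate <- function(v) {
    i <- match(v, e1)
    if (!is.na(i)) return(c(i, 1L))
    i <- match(v, e2)
    if (!is.na(i)) return(c(i, 2L))
    stop("internal: telomere not found on any path")
  }
  assign_side <- function(tel_cap) {
    pa <- integer(p2); sl <- integer(p2)
    for (c in seq_len(p2)) {
      v <- tel_cap[c]
      if (v > 0L) {
        ps <- locate(v)
        pa[c] <- ps[1L]; sl[c] <- ps[2L]
      }
    }
    list(pa = pa, sl = sl)
  }
  sa <- assign_side(capped$tel_cap_a)
  sb <- assign_side(capped$tel_cap_b)
  cap_path_a <- sa$pa; cap_slot_a <- sa$sl
  cap_path_b <- sb$pa; cap_slot_b <- sb$sl
  # dummy adjacencies: unattached caps paired consecutively (by index)
  add_dummies <- function(pa, sl) {
    free <- which(pa == 0L)
    if (length(free) %% 2L != 0L) stop("internal: odd number of free caps")
    if (length(free)) {
      for (k in seq(1L, length(free), by = 2L)) {
        path_runs[[length(path_runs) + 1L]] <<- integer(0)
        path_real <<- c(path_real, FALSE)
        pid <- length(path_runs)
        pa[free[k]] <- pid; sl[free[k]] <- 1L
        pa[free[k + 1L]] <- pid; sl[free[k + 1L]] <- 2L
      }
    }
    list(pa = pa, sl = sl)
  }
  da <- add_dummies(cap_path_a, cap_slot_a)
  cap_path_a <- da$pa; cap_slot_a <- da$sl
  db <- add_dummies(cap_path_b, cap_slot_b)
  cap_path_b <- db$pa; cap_slot_b <- db$sl
  res <- cap_enum_cpp(capped$allowed, cap_path_a, cap_slot_a,
                      cap_path_b, cap_slot_b, path_runs, path_real,
                      max_enum = max_enum)
  if (!isTRUE(res$valid))
    return(list(valid = FALSE))
  d <- length(L) + capped$p + base + res$min_cost
  list(valid = TRUE, d = d, n_capping_sets = res$n_capping_sets,
       n_optimal = res$n_optimal,
       max_paths_single_cycle = res$max_paths_single_cycle,
       best_matching = res$best_matching)
}

#' DCJ-indel distance between two genomes under a fixed ortholog-set
#'
#' Minimum number of DCJ and indel operations transforming `A` into `B`
#' when matched genes are identified by `O` and only the complement genes
#' may be inserted or deleted (no gene is deleted and reinserted).  Computed
#' on the optimally capped relational graph by minimising the cycle/indel-run
#' cost over all capping-sets.
#'
#' @param A,B `ffdcj_genome` objects.
#' @param O Ortholog-set: data.frame/matrix of gene-id pairs (may be empty);
#'   must be a matching between genes of `A` and genes of `B`.
#' @param max_enum Guard on the number of capping-sets enumerated.
#' @return Integer operation count.
#' @examples
#' A <- genome_from_string("A", "[1 2]")
#' B <- genome_from_string("B", "[5 6]")
#' dcj_indel_distance(A, B, cbind(c("1", "2"), c("5", "6")))  # 0
#' @export
dcj_indel_distance <- function(A, B, O, max_enum = 1e7) {
  m <- as_ortholog_pairs(O)
  ga <- gene_table(A)$gene
  gb <- gene_table(B)$gene
  if (nrow(m)) {
    swap <- !(m[, 1] %in% ga & m[, 2] %in% gb) &
      (m[, 1] %in% gb & m[, 2] %in% ga)
    m[swap, ] <- m[swap, c(2, 1)]
    if (any(!(m[, 1] %in% ga)) || any(!(m[, 2] %in% gb)))
      stop("ortholog pairs must connect genes of A and B")
    if (anyDuplicated(m[, 1]) || anyDuplicated(m[, 2]))
      stop("ortholog-set is not a matching")
  }
  S <- similarity_graph(A, B, data.frame(a = m[, 1], b = m[, 2],
                                         sigma = rep(1, nrow(m))))
  ffr <- build_ffr(A, B, S)
  capped <- optimal_capping(ffr)
  L <- seq_len(nrow(m))
  res <- eval_capped_L(capped, L, max_enum = max_enum)
  if (!res$valid) stop("internal: optimal capping found no capping-set")
  as.integer(res$d)
}

#' Weighted DCJ-indel rearrangement distance of an ortholog-set
#'
#' Evaluates `wd = d + |O| - sigma(O) + w(complement(O))`, where `d` is the
#' DCJ-indel distance under `O`, `sigma(O)` the summed similarity scores of
#' the matched pairs and `w(complement(O))` the summed vertex weights of the
#' unmatched genes.
#'
#' @param A,B `ffdcj_genome` objects.
#' @param S An `ffdcj_simgraph` over `A` and `B`.
#' @param O Ortholog-set drawn from the edges of `S`.
#' @param max_enum Guard on capping-set enumeration.
#' @return An object of class `ffdcj_distance` with fields `d`, `o_size`,
#'   `sigma_o`, `w_comp` and `wd`.
#' @export
weighted_distance <- function(A, B, S, O, max_enum = 1e7) {
  ffr <- build_ffr(A, B, S)
  L <- ortholog_set_to_L(ffr, O)
  capped <- optimal_capping(ffr)
  res <- eval_capped_L(capped, L, max_enum = max_enum)
  if (!res$valid) stop("internal: optimal capping found no capping-set")
  distance_report(ffr, L, res$d)
}

distance_report <- function(ffr, L, d) {
  sigma_o <- sum(ffr$sim$sigma[L])
  unmatched_a <- setdiff(seq_len(ffr$nA), ffr$sim$ai[L])
  unmatched_b <- setdiff(seq_len(ffr$nB), ffr$sim$bi[L])
  w_comp <- sum(ffr$w_a[unmatched_a]) + sum(ffr$w_b[unmatched_b])
  structure(list(d = as.integer(d), o_size = length(L),
                 sigma_o = sigma_o, w_comp = w_comp,
                 wd = d + length(L) - sigma_o + w_comp),
            class = "ffdcj_distance")
}

#' @export
print.ffdcj_distance <- function(x, ...) {
  cat("DCJ-indel distance report\n",
      "  d (operations):     ", x$d, "\n",
      "  |O| (orthologs):    ", x$o_size, "\n",
      "  sigma(O):           ", format(x$sigma_o), "\n",
      "  w(complement):      ", format(x$w_comp), "\n",
      "  weighted distance:  ", format(x$wd), "\n", sep = "")
  invisible(x)
}

#' Serialise a distance report as JSON
#' @param report An `ffdcj_distance`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_distance_report <- function(report, path) {
  stopifnot(inherits(report, "ffdcj_distance"))
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Evaluate a capped decomposition over all its capping-sets
#'
#' For a fixed ortholog-set, enumerates every capping-set admitted by the
#' capped graph, reports the minimum DCJ-indel operation count `d`, the
#' number of capping-sets, how many achieve the minimum, and the number of
#' decomposition paths a minimum-cost capping needs to link into a single
#' cycle: among the tied optima, the capping-set whose largest merge is
#' smallest is taken, and its largest merge reported.
#'
#' @param capped An `ffdcj_capped`.
#' @param O Ortholog-set (see [induce_decomposition()]); may be empty.
#' @param max_enum Guard on the number of capping-sets enumerated.
#' @return List with `d`, `n_capping_sets`, `n_optimal`,
#'   `max_paths_single_cycle`.
#' @export
evaluate_capping <- function(capped, O, max_enum = 1e7) {
  stopifnot(inherits(capped, "ffdcj_capped"))
  L <- ortholog_set_to_L(capped$ffr, O)
  res <- eval_capped_L(capped, L, max_enum = max_enum)
  if (!res$valid) stop("capping admits no capping-set (invalid capping)")
  list(d = as.integer(res$d), n_capping_sets = res$n_capping_sets,
       n_optimal = res$n_optimal,
       max_paths_single_cycle = res$max_paths_single_cycle)
}

#' Enumerate all ortholog-sets of a relational graph
#'
#' All matchings of the underlying gene similarity graph (including the
#' empty one), for exhaustive analyses of tiny instances.
#'
#' @param ffr An `ffdcj_ffr`.
#' @param max_sets Guard on the number of matchings.
#' @return List of data.frames with columns `a`, `b`.
#' @export
enumerate_ortholog_sets <- function(ffr, max_sets = 1e6) {
  stopifnot(inherits(ffr, "ffdcj_ffr"))
  lapply(enumerate_sibling_sets(ffr, max_sets = max_sets), function(L)
    data.frame(a = ffr$gene_a[ffr$sim$ai[L]],
               b = ffr$gene_b[ffr$sim$bi[L]], stringsAsFactors = FALSE))
}
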