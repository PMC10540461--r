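# Capping of the family-free relational graph: cap vertices close the paths
# of every consistent decomposition into cycles.  Optimal capping connects
# every segment end of one genome to every segment end of the other; the
# heuristic capping restricts connections to content-related segments via
# the shared-content graph.

new_capped <- function(ffr, mode, p, tel_cap_a, tel_cap_b, allowed,
                       content = NULL) {
  n_cap_edges <- sum(allowed)
  lperm <- NA_real_
  nperm <- NA_real_
  if (2L * p <= 16L) {
    nperm <- permanent_cpp(matrix(as.numeric(allowed), 2L * p, 2L * p))
    lperm <- log(nperm)
  } else if (mode == "optimal") {
    nperm <- factorial(2L * p)
    lperm <- lfactorial(2L * p)
  }
  structure(list(ffr = ffr, mode = mode, p = p,
                 tel_cap_a = tel_cap_a, tel_cap_b = tel_cap_b,
                 allowed = allowed, content = content,
                 n_cap_edges = n_cap_edges,
                 n_capping_sets = nperm, log_capping_sets = lperm),
            class = "ffdcj_capped")
}

#' @export
print.ffdcj_capped <- function(x, ...) {
  cat("Capped relational graph (", x$mode, " capping)\n",
      "  cap vertices per genome: ", 2L * x$p, "\n",
      "  cap edges:               ", x$n_cap_edges, "\n", sep = "")
  if (is.finite(x$n_capping_sets))
    cat("  capping-sets:            ", format(x$n_capping_sets), "\n",
        sep = "")
  else
    cat("  capping-sets:            ", factorial_display(x$log_capping_sets),
        "\n", sep = "")
  invisible(x)
}

# Display a log-count as the nearest "k!"
factorial_display <- function(log_count) {
  if (!is.finite(log_count)) return("unknown")
  k <- 1
  while (lfactorial(k + 1) <= log_count) k <- k + 1
  paste0("~", k, "!")
}

#' Optimal capping of a relational graph
#'
#' Adds `2 p` cap vertices per genome with `p = max(kappa(A), kappa(B))`,
#' attaches every telomere to its own cap vertex, pairs the remaining
#' (equalising) cap vertices of the smaller genome consecutively by index
#' into dummy adjacencies, and connects all cap vertices of one genome to
#' all of the other (complete bipartite cap-edge set), so that every one of
#' the `(2p)!` perfect matchings of cap vertices is an admissible
#' capping-set.
#'
#' @param ffr An `ffdcj_ffr`.
#' @return An `ffdcj_capped` object.
#' @export
optimal_capping <- function(ffr) {
  stopifnot(inherits(ffr, "ffdcj_ffr"))
  kA <- kappa(ffr$A)
  kB <- kappa(ffr$B)
  p <- max(kA, kB)
  tel_cap_a <- c(ffr$telomeres_a, rep(0L, 2L * (p - kA)))
  tel_cap_b <- c(ffr$telomeres_b, rep(0L, 2L * (p - kB)))
  allowed <- matrix(TRUE, 2L * p, 2L * p)
  new_capped(ffr, "optimal", p, tel_cap_a, tel_cap_b, allowed)
}

#' Shared-content graph of two genomes
#'
#' Bipartite graph on the linear segments of `A` and `B`, with an edge AB of
#' score `Omega(A, B)` = summed similarity scores between genes of segment A
#' and genes of segment B, for all pairs with positive shared content.  Two
#' filters then remove edges: (i) an edge survives the tau-filter iff it is
#' among the `tau` highest-scored edges of both of its endpoints (ties at
#' rank tau kept, ranks on the unfiltered graph); (ii) with
#' `Omega(v)` = the maximum surviving score at `v`, every remaining edge
#' incident to a vertex `v` with score below `eps * Omega(v)` is removed.
#'
#' @param A,B `ffdcj_genome` objects.
#' @param S An `ffdcj_simgraph` over `A` and `B`.
#' @param tau Positive integer rank threshold (default 2).
#' @param eps Relative score threshold in (0, 1] (default 0.1).
#' @return An object of class `ffdcj_scg` with segment vertex sets and the
#'   filtered `Omega`-scored edge list.
#' @export
build_shared_content_graph <- function(A, B, S, tau = 2L, eps = 0.1) {
  stopifnot(inherits(A, "ffdcj_genome"), inherits(B, "ffdcj_genome"),
            inherits(S, "ffdcj_simgraph"))
  stopifnot(tau >= 1L, eps > 0, eps <= 1)
  ta <- gene_table(A)
  tb <- gene_table(B)
  seg_a <- names(A$segments)
  seg_b <- names(B$segments)
  edges <- S$edges
  if (nrow(edges)) {
    sa <- ta$segment[match(edges$a, ta$gene)]
    sb <- tb$segment[match(edges$b, tb$gene)]
    key <- paste(sa, sb, sep = "\r")
    om <- tapply(edges$sigma, key, sum)
    parts <- strsplit(names(om), "\r", fixed = TRUE)
    F <- data.frame(a = vapply(parts, `[[`, character(1), 1L),
                    b = vapply(parts, `[[`, character(1), 2L),
                    omega = as.numeric(om), stringsAsFactors = FALSE)
  } else {
    F <- data.frame(a = character(0), b = character(0), omega = numeric(0))
  }
  # tau-filter: edge kept iff within the tau best (with ties) of both ends
  if (nrow(F)) {
    ok <- rep(TRUE, nrow(F))
    for (side in c("a", "b")) {
      for (v in unique(F[[side]])) {
        i <- which(F[[side]] == v)
        sc <- sort(F$omega[i], decreasing = TRUE)
        if (length(i) > tau) {
          thr <- sc[tau]  # ties at rank tau all kept
          ok[i][F$omega[i] < thr] <- FALSE
        }
      }
    }
    F <- F[ok, , drop = FALSE]
  }
  # eps-filter on the surviving graph
  if (nrow(F)) {
    omega_v <- c(tapply(F$omega, F$a, max), tapply(F$omega, F$b, max))
    keep <- F$omega >= eps * pmax(as.numeric(omega_v[F$a]),
                                  as.numeric(omega_v[F$b]))
    F <- F[keep, , drop = FALSE]
  }
  rownames(F) <- NULL
  structure(list(seg_a = seg_a, seg_b = seg_b,
                 dummy_a = character(0), dummy_b = character(0),
                 edges = F, tau = tau, eps = eps, perfect = FALSE),
            class = "ffdcj_scg")
}

#' @export
print.ffdcj_scg <- function(x, ...) {
  cat("Shared-content graph: ", length(x$seg_a), "+", length(x$dummy_a),
      " vs ", length(x$seg_b), "+", length(x$dummy_b),
      " segments (+dummies), ", nrow(x$edges), " edges",
      if (x$perfect) " [perfect]" else "", "\n", sep = "")
  invisible(x)
}

#' Write a shared-content graph as TSV
#' @param C An `ffdcj_scg`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_shared_content <- function(C, path) {
  stopifnot(inherits(C, "ffdcj_scg"))
  utils::write.table(C$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

scg_sides <- function(C) {
  list(a = c(C$seg_a, C$dummy_a), b = c(C$seg_b, C$dummy_b))
}

scg_biadjacency <- function(C) {
  s <- scg_sides(C)
  m <- matrix(FALSE, length(s$a), length(s$b),
              dimnames = list(s$a, s$b))
  if (nrow(C$edges))
    m[cbind(match(C$edges$a, s$a), match(C$edges$b, s$b))] <- TRUE
  m
}

scg_max_matching <- function(C) {
  m <- scg_biadjacency(C)
  res <- bip_max_matching_cpp(m)
  s <- scg_sides(C)
  matched <- which(res$match_left > 0L)
  data.frame(a = s$a[matched], b = s$b[res$match_left[matched]],
             stringsAsFactors = FALSE)
}

#' Find a Hall violator set from an unsaturated vertex
#'
#' Given a bipartite shared-content graph, a maximum matching and a vertex
#' `v` unsaturated by it, returns the Hall violator
#' `S = {v} + {u on v's side reachable from v by an M-alternating path}`,
#' which satisfies `|N(S)| < |S|`.
#'
#' @param C An `ffdcj_scg`.
#' @param M Matching as a data.frame with columns `a`, `b` (as returned by
#'   the internal maximum matching); must be a maximum matching.
#' @param v Segment id unsaturated by `M`.
#' @return Character vector of segment ids on `v`'s side.
#' @export
find_hall_violator <- function(C, M, v) {
  stopifnot(inherits(C, "ffdcj_scg"))
  s <- scg_sides(C)
  side <- if (v %in% s$a) "a" else if (v %in% s$b) "b" else
    stop("unknown segment: ", v)
  if (v %in% M[[side]]) stop("vertex '", v, "' is saturated by M")
  own <- s[[side]]
  opp <- s[[if (side == "a") "b" else "a"]]
  E <- C$edges
  nbr <- function(u) {
    if (side == "a") unique(E$b[E$a == u]) else unique(E$a[E$b == u])
  }
  mate <- stats::setNames(M[[side]], M[[if (side == "a") "b" else "a"]])
  S <- v
  frontier <- v
  seen_opp <- character(0)
  while (length(frontier)) {
    reach_opp <- setdiff(unique(unlist(lapply(frontier, nbr))), seen_opp)
    seen_opp <- c(seen_opp, reach_opp)
    # follow matching edges back to v's side
    back <- unname(mate[reach_opp[reach_opp %in% names(mate)]])
    frontier <- setdiff(back, S)
    S <- c(S, frontier)
  }
  sort(S)
}

scg_neighbourhood <- function(C, S, side) {
  E <- C$edges
  if (side == "a") sort(unique(E$b[E$a %in% S]))
  else sort(unique(E$a[E$b %in% S]))
}

#' Complete a shared-content graph to a perfect shared-content graph
#'
#' Iteratively adds dummy segments until a perfect matching exists: while
#' the maximum matching is not perfect, an unsaturated vertex yields a Hall
#' violator `S`, and `|S| - |N(S)|` dummy segments are created on the
#' opposite side, each connected to every segment of `S` (dummy edges carry
#' no content score and are exempt from the tau/eps filters).  Finally all
#' non-matchable edges (edges in no perfect matching) are removed.
#'
#' @param C An `ffdcj_scg`.
#' @return An `ffdcj_scg` with `perfect = TRUE`, equal-size sides, and only
#'   matchable edges.
#' @export
complete_to_perfect <- function(C) {
  stopifnot(inherits(C, "ffdcj_scg"))
  repeat {
    s <- scg_sides(C)
    M <- scg_max_matching(C)
    if (nrow(M) == length(s$a) && nrow(M) == length(s$b)) break
    # pick an unsaturated vertex, preferring the larger side
    un_a <- setdiff(s$a, M$a)
    un_b <- setdiff(s$b, M$b)
    pick <- if (length(un_a) >= length(un_b)) {
      list(v = un_a[1], side = "a")
    } else list(v = un_b[1], side = "b")
    S <- find_hall_violator(C, M, pick$v)
    NS <- scg_neighbourhood(C, S, pick$side)
    n_new <- length(S) - length(NS)
    stopifnot(n_new >= 1L)
    opp_side <- if (pick$side == "a") "b" else "a"
    dummy_slot <- paste0("dummy_", opp_side)
    existing <- length(C[[dummy_slot]])
    ids <- paste0("phi_", toupper(opp_side), "_",
                  existing + seq_len(n_new))
    C[[dummy_slot]] <- c(C[[dummy_slot]], ids)
    new_edges <- expand.grid(d = ids, s = S, stringsAsFactors = FALSE)
    add <- if (pick$side == "a") {
      data.frame(a = new_edges$s, b = new_edges$d, omega = NA_real_)
    } else {
      data.frame(a = new_edges$d, b = new_edges$s, omega = NA_real_)
    }
    C$edges <- rbind(C$edges, add)
  }
  C <- prune_non_matchable(C)
  C$perfect <- TRUE
  C
}

#' Remove non-matchable edges from a bipartite graph with a perfect matching
#'
#' An edge is matchable if it belongs to at least one perfect matching.
#' Identification uses the standard orientation argument: orient matched
#' edges one way and unmatched edges the other; an unmatched edge is
#' matchable iff it lies on a directed cycle, i.e. its endpoints are in the
#' same strongly connected component.
#'
#' @param C An `ffdcj_scg` admitting at least one perfect matching.
#' @return The graph with exactly the matchable edges kept.
#' @export
prune_non_matchable <- function(C) {
  stopifnot(inherits(C, "ffdcj_scg"))
  s <- scg_sides(C)
  if (length(s$a) != length(s$b))
    stop("graph sides differ in size; no perfect matching")
  M <- scg_max_matching(C)
  if (nrow(M) != length(s$a))
    stop("graph admits no perfect matching")
  n <- length(s$a)
  if (n == 0L) return(C)
  # directed graph on 2n nodes: a_i -> b_j for matched (i,j),
  # b_j -> a_i for unmatched edges (i,j)
  idx_a <- stats::setNames(seq_len(n), s$a)
  idx_b <- stats::setNames(n + seq_len(n), s$b)
  E <- C$edges
  mkey <- paste(M$a, M$b, sep = "\r")
  ekey <- paste(E$a, E$b, sep = "\r")
  in_m <- ekey %in% mkey
  from <- ifelse(in_m, idx_a[E$a], idx_b[E$b])
  to <- ifelse(in_m, idx_b[E$b], idx_a[E$a])
  comp <- scc_tarjan(2L * n, from, to)
  keep <- in_m | comp[idx_a[E$a]] == comp[idx_b[E$b]]
  C$edges <- E[keep, , drop = FALSE]
  rownames(C$edges) <- NULL
  C
}

# Iterative Tarjan strongly-connected components on nodes 1..n.
scc_tarjan <- function(n, from, to) {
  adj <- vector("list", n)
  for (k in seq_along(from)) adj[[from[k]]] <- c(adj[[from[k]]], to[k])
  index <- rep(NA_integer_, n)
  low <- integer(n)
  onstack <- logical(n)
  stack <- integer(0)
  comp <- integer(n)
  counter <- 0L
  ncomp <- 0L
  for (root in seq_len(n)) {
    if (!is.na(index[root])) next
    # iterative DFS with explicit frames: (node, child pointer)
    frames <- list(list(v = root, i = 0L))
    while (length(frames)) {
      f <- frames[[length(frames)]]
      v <- f$v
      if (f$i == 0L) {
        counter <- counter + 1L
        index[v] <- low[v] <- counter
        stack <- c(stack, v)
        onstack[v] <- TRUE
      } else {
        w <- adj[[v]][f$i]
        low[v] <- min(low[v], low[w])
      }
      advanced <- FALSE
      nb <- adj[[v]]
      i <- f$i
      while (i < length(nb)) {
        i <- i + 1L
        w <- nb[i]
        if (is.na(index[w])) {
          frames[[length(frames)]]$i <- i
          frames[[length(frames) + 1L]] <- list(v = w, i = 0L)
          advanced <- TRUE
          break
        } else if (onstack[w]) {
          low[v] <- min(low[v], index[w])
        }
      }
      if (!advanced) {
        if (low[v] == index[v]) {
          ncomp <- ncomp + 1L
          repeat {
            w <- stack[length(stack)]
            stack <- stack[-length(stack)]
            onstack[w] <- FALSE
            comp[w] <- ncomp
            if (w == v) break
          }
        }
        frames[[length(frames)]] <- NULL
      }
    }
  }
  comp
}

# Connected components of the shared-content graph (segment level).
scg_components <- function(C) {
  s <- scg_sides(C)
  nodes <- c(paste0("a\r", s$a), paste0("b\r", s$b))
  # component labels by repeated relabelling (graphs are small)
  lab <- stats::setNames(seq_along(nodes), nodes)
  E <- C$edges
  if (nrow(E)) {
    repeat {
      changed <- FALSE
      la <- lab[paste0("a\r", E$a)]
      lb <- lab[paste0("b\r", E$b)]
      mn <- pmin(la, lb)
      if (any(la != mn)) { lab[paste0("a\r", E$a)] <- mn; changed <- TRUE }
      if (any(lb != mn)) { lab[paste0("b\r", E$b)] <- mn; changed <- TRUE }
      if (!changed) break
    }
  }
  split(nodes, lab[nodes])
}

# Cap-edge matrix induced by a (perfect) shared-content graph.
# Segments of side A occupy caps (2i-1, 2i) in the order seg_a then dummy_a.
cap_matrix_from_scg <- function(C) {
  s <- scg_sides(C)
  pa <- length(s$a)
  pb <- length(s$b)
  allowed <- matrix(FALSE, 2L * pa, 2L * pb)
  E <- C$edges
  if (nrow(E)) {
    ia <- match(E$a, s$a)
    ib <- match(E$b, s$b)
    deg_a <- table(E$a)
    deg_b <- table(E$b)
    for (k in seq_along(ia)) {
      i <- ia[k]; j <- ib[k]
      single <- deg_a[[E$a[k]]] == 1L && deg_b[[E$b[k]]] == 1L
      is_dummy <- E$a[k] %in% C$dummy_a || E$b[k] %in% C$dummy_b
      if (single && is_dummy) {
        # both ends of a dummy segment are equivalent: keep one crosswise pair
        allowed[2L * i - 1L, 2L * j - 1L] <- TRUE
        allowed[2L * i, 2L * j] <- TRUE
      } else {
        allowed[2L * i - 1L, 2L * j - 1L] <- TRUE
        allowed[2L * i, 2L * j] <- TRUE
        allowed[2L * i - 1L, 2L * j] <- TRUE
        allowed[2L * i, 2L * j - 1L] <- TRUE
      }
    }
  }
  allowed
}

#' Heuristic capping induced by a perfect shared-content graph
#'
#' Adds `2 p` cap vertices per genome with `p` the common side size of the
#' perfect shared-content graph.  The two telomeres of the i-th real segment
#' attach to cap vertices `2i-1` and `2i`; each dummy segment becomes a
#' dummy adjacency between its two cap vertices; for every edge AB of the
#' graph the two crosswise cap-pairings contribute 4 cap edges, except for
#' single-edge components with a dummy endpoint, which keep only one
#' crosswise pairing.
#'
#' @param ffr An `ffdcj_ffr`.
#' @param C_hat A perfect `ffdcj_scg` (see [complete_to_perfect()]).
#' @return An `ffdcj_capped` object.
#' @export
heuristic_capping <- function(ffr, C_hat) {
  stopifnot(inherits(ffr, "ffdcj_ffr"), inherits(C_hat, "ffdcj_scg"))
  s <- scg_sides(C_hat)
  if (length(s$a) != length(s$b))
    stop("shared-content graph sides differ; complete it first")
  M <- scg_max_matching(C_hat)
  if (nrow(M) != length(s$a))
    stop("shared-content graph admits no perfect matching; capping invalid")
  if (!identical(sort(C_hat$seg_a), sort(names(ffr$A$segments))) ||
      !identical(sort(C_hat$seg_b), sort(names(ffr$B$segments))))
    stop("shared-content graph does not match the genomes of the ffr")
  p <- length(s$a)
  # telomeres in cap order: segment i of the scg ordering -> caps 2i-1, 2i
  tel_of_segment <- function(genome, telomeres) {
    segs <- names(genome$segments)
    m <- matrix(telomeres, ncol = 2L, byrow = TRUE)
    rownames(m) <- segs
    m
  }
  ma <- tel_of_segment(ffr$A, ffr$telomeres_a)
  mb <- tel_of_segment(ffr$B, ffr$telomeres_b)
  tel_cap_a <- integer(2L * p)
  tel_cap_b <- integer(2L * p)
  for (i in seq_along(s$a)) {
    sid <- s$a[i]
    if (sid %in% rownames(ma)) {
      tel_cap_a[2L * i - 1L] <- ma[sid, 1L]
      tel_cap_a[2L * i] <- ma[sid, 2L]
    }
  }
  for (j in seq_along(s$b)) {
    sid <- s$b[j]
    if (sid %in% rownames(mb)) {
      tel_cap_b[2L * j - 1L] <- mb[sid, 1L]
      tel_cap_b[2L * j] <- mb[sid, 2L]
    }
  }
  allowed <- cap_matrix_from_scg(C_hat)
  new_capped(ffr, "heuristic", p, tel_cap_a, tel_cap_b, allowed,
             content = C_hat)
}

#' Upper bound on the number of capping-sets of a perfect shared-content graph
#'
#' Bregman-Minc bound on the permanent of the biadjacency matrix:
#' `prod_i (r_i!)^(1/r_i)` over the row degrees `r_i`.  For small graphs the
#' exact permanent (Ryser's formula) is also reported.
#'
#' @param C_hat A square `ffdcj_scg`.
#' @param exact_limit Compute the exact permanent when the side size is at
#'   most this (default 8).
#' @return List with `bound`, `log_bound`, `exact` (or `NA`), `display`
#'   (factorial-style magnitude, e.g. `"~45!"`).
#' @export
capping_search_space_bound <- function(C_hat, exact_limit = 8L) {
  stopifnot(inherits(C_hat, "ffdcj_scg"))
  m <- scg_biadjacency(C_hat)
  if (nrow(m) != ncol(m)) stop("graph is not square")
  r <- rowSums(m)
  if (any(r == 0)) {
    bound <- 0
    log_bound <- -Inf
  } else {
    log_bound <- sum(lfactorial(r) / r)
    bound <- exp(log_bound)
  }
  exact <- if (nrow(m) <= exact_limit)
    permanent_cpp(matrix(as.numeric(m), nrow(m))) else NA_real_
  list(bound = bound, log_bound = log_bound, exact = exact,
       display = factorial_display(log_bound))
}

#' Capping report
#'
#' Summarises a capped relational graph (cap-edge count, component count of
#' the content graph where applicable, capping-set counts/bounds) and
#' optionally writes it as JSON.
#'
#' @param capped An `ffdcj_capped`.
#' @param path Optional output path for a JSON report.
#' @return A list (invisibly if written).
#' @export
capping_report <- function(capped, path = NULL) {
  stopifnot(inherits(capped, "ffdcj_capped"))
  rep <- list(mode = capped$mode, p = capped$p,
              n_cap_vertices_per_genome = 2L * capped$p,
              n_cap_edges = capped$n_cap_edges,
              n_capping_sets = capped$n_capping_sets,
              log_capping_sets = capped$log_capping_sets,
              display = factorial_display(capped$log_capping_sets))
  if (!is.null(capped$content))
    rep$n_content_components <- length(scg_components(capped$content))
  if (!is.null(path)) {
    jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA)
    return(invisible(rep))
  }
  rep
}
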