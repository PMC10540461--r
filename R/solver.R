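# Exact solver for the family-free DCJ-indel optimisation: minimise the
# weighted rearrangement distance over all sibling-sets of the relational
# graph and all capping-sets of its capped extension.  A branch-and-bound
# over ortholog matchings with exhaustive capping-set enumeration per leaf;
# exact, with the optimum of an integer programme but no external solver.

#' Solver configuration
#'
#' @param time_limit Wall-clock limit in minutes; defaults to 60 for
#'   heuristic capping and 1440 for optimal capping when `NULL`.
#' @param max_enum Guard on the number of capping-sets enumerated per
#'   sibling-set.
#' @param max_nodes Guard on branch-and-bound nodes.
#' @return A list of class `ffdcj_solver_config`.
#' @export
solver_config <- function(time_limit = NULL, max_enum = 1e7,
                          max_nodes = 1e7) {
  stopifnot(is.null(time_limit) || time_limit > 0)
  structure(list(time_limit = time_limit, max_enum = max_enum,
                 max_nodes = max_nodes), class = "ffdcj_solver_config")
}

# All matchings (sibling-sets) of the similarity graph of an ffr,
# as a list of integer vectors of similarity-edge indices.
enumerate_sibling_sets <- function(ffr, max_sets = 1e6) {
  ne <- nrow(ffr$sim)
  out <- list()
  if (ne == 0L) return(list(integer(0)))
  ai <- ffr$sim$ai
  bi <- ffr$sim$bi
  recurse <- function(i, chosen, used_a, used_b) {
    if (i > ne) {
      out[[length(out) + 1L]] <<- chosen
      if (length(out) > max_sets) stop("too many sibling-sets")
      return(invisible(NULL))
    }
    recurse(i + 1L, chosen, used_a, used_b)
    if (!(ai[i] %in% used_a) && !(bi[i] %in% used_b))
      recurse(i + 1L, c(chosen, i), c(used_a, ai[i]), c(used_b, bi[i]))
    invisible(NULL)
  }
  recurse(1L, integer(0), integer(0), integer(0))
  out  # every matching exactly once, including the empty one
}

# Weight-term cost of a sibling-set: |O| - sigma(O) + w(complement).
weight_cost <- function(ffr, L) {
  sigma_o <- sum(ffr$sim$sigma[L])
  unmatched_a <- setdiff(seq_len(ffr$nA), ffr$sim$ai[L])
  unmatched_b <- setdiff(seq_len(ffr$nB), ffr$sim$bi[L])
  length(L) - sigma_o + sum(ffr$w_a[unmatched_a]) + sum(ffr$w_b[unmatched_b])
}

make_solution <- function(capped, L, eval, status, n_nodes = NA_integer_,
                          n_leaves = NA_integer_) {
  ffr <- capped$ffr
  report <- distance_report(ffr, L, eval$d)
  os <- data.frame(a = ffr$gene_a[ffr$sim$ai[L]],
                   b = ffr$gene_b[ffr$sim$bi[L]],
                   sigma = ffr$sim$sigma[L], stringsAsFactors = FALSE)
  os <- os[order(os$a, os$b), , drop = FALSE]
  rownames(os) <- NULL
  structure(list(ortholog_set = os, L = sort(L), report = report,
                 status = status, mode = capped$mode,
                 capping_set = eval$best_matching,
                 n_capping_sets = eval$n_capping_sets,
                 max_paths_single_cycle = eval$max_paths_single_cycle,
                 n_nodes = n_nodes, n_leaves = n_leaves),
            class = "ffdcj_solution")
}

#' @export
print.ffdcj_solution <- function(x, ...) {
  cat("Family-free DCJ-indel solution (", x$mode, " capping, status: ",
      x$status, ")\n", sep = "")
  cat("  orthologs: ", nrow(x$ortholog_set), ", d = ", x$report$d,
      ", wd = ", format(x$report$wd), "\n", sep = "")
  invisible(x)
}

#' Solve the family-free DCJ-indel problem on a capped relational graph
#'
#' Minimises the weighted rearrangement distance
#' `wd = d + |O| - sigma(O) + w(complement(O))` jointly over all
#' sibling-sets of the relational graph and all capping-sets admitted by
#' the capped graph, by branch-and-bound over ortholog matchings with
#' exhaustive capping-set enumeration at the leaves.  Ties between
#' equally-optimal ortholog-sets break towards the lexicographically
#' smallest edge list, making results reproducible.
#'
#' @param capped An `ffdcj_capped` (see [optimal_capping()],
#'   [heuristic_capping()]).
#' @param config An [solver_config()].
#' @return An `ffdcj_solution`; `status` is `"optimal"` or
#'   `"feasible-at-timeout"` (best incumbent when a guard was hit).
#' @export
solve_capped_ffr <- function(capped, config = solver_config()) {
  stopifnot(inherits(capped, "ffdcj_capped"),
            inherits(config, "ffdcj_solver_config"))
  ffr <- capped$ffr
  tl <- config$time_limit
  if (is.null(tl)) tl <- if (capped$mode == "heuristic") 60 else 1440
  deadline <- Sys.time() + tl * 60
  sim <- ffr$sim
  nA <- ffr$nA
  # per A-gene incident edges, cheapest-first
  inc <- lapply(seq_len(nA), function(g) which(sim$ai == g))
  # optimistic per-gene contribution (admissible bound, ignores d >= 0)
  opt_a <- vapply(seq_len(nA), function(g) {
    if (length(inc[[g]])) min(ffr$w_a[g], min(1 - sim$sigma[inc[[g]]]))
    else ffr$w_a[g]
  }, numeric(1))
  suffix_bound <- rev(cumsum(rev(c(opt_a, 0))))  # bound for genes g..nA
  best_wd <- Inf
  best_L <- NULL
  best_eval <- NULL
  n_nodes <- 0L
  n_leaves <- 0L
  hit_guard <- FALSE
  used_b <- logical(ffr$nB)
  evaluate_leaf <- function(L) {
    n_leaves <<- n_leaves + 1L
    ev <- eval_capped_L(capped, L, max_enum = config$max_enum)
    if (!ev$valid) stop("capping admits no capping-set (invalid capping)")
    wd <- ev$d + weight_cost(ffr, L)
    Ls <- sort(L)
    better <- wd < best_wd - 1e-9 ||
      (abs(wd - best_wd) <= 1e-9 && !is.null(best_L) &&
         lex_less(Ls, sort(best_L)))
    if (is.null(best_L) || better) {
      best_wd <<- wd
      best_L <<- Ls
      best_eval <<- ev
    }
  }
  recurse <- function(g, L, committed) {
    n_nodes <<- n_nodes + 1L
    if (n_nodes > config$max_nodes || Sys.time() > deadline) {
      hit_guard <<- TRUE
      return(invisible(NULL))
    }
    if (g > nA) {
      evaluate_leaf(L)
      return(invisible(NULL))
    }
    if (committed + suffix_bound[g] >= best_wd + 1e-9)
      return(invisible(NULL))
    # try matching gene g through each incident edge, then leaving it
    for (e in inc[[g]]) {
      if (!used_b[sim$bi[e]]) {
        used_b[sim$bi[e]] <<- TRUE
        recurse(g + 1L, c(L, e), committed + (1 - sim$sigma[e]))
        used_b[sim$bi[e]] <<- FALSE
        if (hit_guard) return(invisible(NULL))
      }
    }
    recurse(g + 1L, L, committed + ffr$w_a[g])
    invisible(NULL)
  }
  recurse(1L, integer(0), 0)
  if (is.null(best_L)) stop("no feasible solution found within guards")
  status <- if (hit_guard) "feasible-at-timeout" else "optimal"
  make_solution(capped, best_L, best_eval, status, n_nodes, n_leaves)
}

lex_less <- function(x, y) {
  n <- min(length(x), length(y))
  if (n) {
    for (i in seq_len(n)) {
      if (x[i] < y[i]) return(TRUE)
      if (x[i] > y[i]) return(FALSE)
    }
  }
  length(x) < length(y)
}

#' Exhaustively solve a capped relational graph (tiny instances)
#'
#' Enumerates every sibling-set and, for each, every capping-set, returning
#' the global minimum of the weighted distance.  Guarded to tiny instances;
#' serves as the reference the branch-and-bound solver is checked against.
#'
#' @param capped An `ffdcj_capped`.
#' @param max_edges,max_segments Guards: at most this many similarity edges
#'   and total linear segments.
#' @param max_enum Guard on capping-set enumeration.
#' @return An `ffdcj_solution` with `status = "optimal"`.
#' @export
exhaustive_solve <- function(capped, max_edges = 8L, max_segments = 6L,
                             max_enum = 1e7) {
  stopifnot(inherits(capped, "ffdcj_capped"))
  ffr <- capped$ffr
  if (nrow(ffr$sim) > max_edges)
    stop("instance above guard: ", nrow(ffr$sim), " similarity edges")
  if (kappa(ffr$A) + kappa(ffr$B) > max_segments)
    stop("instance above guard: too many segments")
  sets <- enumerate_sibling_sets(ffr)
  best <- NULL
  best_wd <- Inf
  best_L <- NULL
  for (L in sets) {
    ev <- eval_capped_L(capped, L, max_enum = max_enum)
    if (!ev$valid) stop("capping admits no capping-set (invalid capping)")
    wd <- ev$d + weight_cost(ffr, L)
    Ls <- sort(L)
    if (wd < best_wd - 1e-9 ||
        (abs(wd - best_wd) <= 1e-9 && !is.null(best_L) &&
           lex_less(Ls, best_L))) {
      best_wd <- wd
      best_L <- Ls
      best <- ev
    }
  }
  make_solution(capped, best_L, best, "optimal",
                n_leaves = length(sets))
}

#' Pairwise family-free comparison of two genomes
#'
#' Full pairwise pipeline: build the filtered gene similarity graph, the
#' family-free relational graph, cap it (optimally, or heuristically via the
#' shared-content graph completed to a perfect one), and solve for an
#' optimal ortholog-set.
#'
#' @param A,B `ffdcj_genome` objects.
#' @param hits `ffdcj_hits` bitscore table covering the two genomes
#'   (including self hits).  Alternatively pass a prebuilt similarity graph
#'   via `S`.
#' @param mode `"heuristic"` (default) or `"optimal"` capping.
#' @param f_eps,f_t Similarity filter thresholds (see
#'   [build_similarity_graph()]).
#' @param tau,eps Shared-content filter thresholds (see
#'   [build_shared_content_graph()]).
#' @param S Optional `ffdcj_simgraph` overriding `hits`.
#' @param config An [solver_config()].
#' @return A list of class `ffdcj_pair` with the solution and the
#'   intermediate graphs.
#' @export
gendiff_pair <- function(A, B, hits = NULL, mode = c("heuristic", "optimal"),
                         f_eps = 0.1, f_t = 0.8, tau = 2L, eps = 0.1,
                         S = NULL, config = solver_config()) {
  mode <- match.arg(mode)
  if (is.null(S)) {
    if (is.null(hits)) stop("provide either hits or a similarity graph S")
    S <- build_similarity_graph(A, B, hits, f_eps = f_eps, f_t = f_t)
  }
  ffr <- build_ffr(A, B, S)
  scg <- NULL
  if (mode == "optimal") {
    capped <- optimal_capping(ffr)
  } else {
    scg <- complete_to_perfect(build_shared_content_graph(A, B, S,
                                                          tau = tau,
                                                          eps = eps))
    capped <- heuristic_capping(ffr, scg)
  }
  sol <- solve_capped_ffr(capped, config = config)
  structure(list(solution = sol, S = S, ffr = ffr, capped = capped,
                 content = scg),
            class = "ffdcj_pair")
}

#' @export
print.ffdcj_pair <- function(x, ...) {
  cat("Pairwise comparison ", x$S$genome_a, " vs ", x$S$genome_b, "\n",
      sep = "")
  print(x$solution)
  invisible(x)
}

#' Write a solution as JSON and its ortholog pairs as TSV
#'
#' @param sol An `ffdcj_solution`.
#' @param json_path,tsv_path Output paths (either may be `NULL`).
#' @return Invisibly, the solution.
#' @export
write_solution <- function(sol, json_path = NULL, tsv_path = NULL) {
  stopifnot(inherits(sol, "ffdcj_solution"))
  if (!is.null(json_path)) {
    jsonlite::write_json(list(
      status = sol$status, mode = sol$mode,
      d = sol$report$d, o_size = sol$report$o_size,
      sigma_o = sol$report$sigma_o, w_comp = sol$report$w_comp,
      wd = sol$report$wd, n_capping_sets = sol$n_capping_sets
    ), json_path, auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(tsv_path)) {
    utils::write.table(sol$ortholog_set, tsv_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(sol)
}
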