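# Orchestration: all pairwise comparisons of n genomes, integration into
# families, optional MCL refinement, evaluation, and worked-example
# fixtures.

#' Run the complete orthology-inference pipeline
#'
#' For each of the n(n-1)/2 genome pairs: build the filtered gene
#' similarity graph, the family-free relational graph, cap it (optimal or
#' heuristic capping) and solve for an optimal ortholog-set; then integrate
#' all pairwise ortholog-sets into the n-partite family graph, classify the
#' connected components into families and optionally refine ambiguous
#' families by Markov clustering.  A failing pair is recorded and the
#' remaining pairs continue.
#'
#' @param genomes Named list of `ffdcj_genome` (>= 2).
#' @param hits `ffdcj_hits` table covering all genomes (self hits
#'   included).
#' @param mode `"heuristic"` (default) or `"optimal"` capping.
#' @param f_eps,f_t Similarity filter thresholds.
#' @param tau,eps Shared-content filter thresholds (heuristic capping).
#' @param mcl Refine ambiguous families with Markov clustering (default
#'   TRUE).
#' @param inflation MCL inflation, default 1.4.
#' @param config [solver_config()] passed to every pairwise solve.
#' @param out_dir Optional directory: families, per-pair ortholog TSVs and
#'   reports are written there.
#' @return An object of class `ffdcj_pipeline_result` with `families`
#'   (classified, after optional refinement), `families_raw`,
#'   `family_set`, per-pair `solutions`, `errors` and `timings`.
#' @export
run_pipeline <- function(genomes, hits, mode = c("heuristic", "optimal"),
                         f_eps = 0.1, f_t = 0.8, tau = 2L, eps = 0.1,
                         mcl = TRUE, inflation = 1.4,
                         config = solver_config(), out_dir = NULL) {
  mode <- match.arg(mode)
  stopifnot(is.list(genomes))
  if (length(genomes) < 2L)
    stop("the pipeline needs at least 2 genomes")
  if (is.null(names(genomes)))
    names(genomes) <- vapply(genomes, `[[`, character(1), "genome_id")
  gn <- names(genomes)
  solutions <- list()
  errors <- list()
  timings <- list()
  pairwise <- list()
  for (i in seq_len(length(gn) - 1L)) {
    for (j in (i + 1L):length(gn)) {
      key <- paste(gn[i], gn[j], sep = "|")
      t0 <- Sys.time()
      pair_genes <- c(gene_table(genomes[[i]])$gene,
                      gene_table(genomes[[j]])$gene)
      pair_hits <- hits[hits$query %in% pair_genes &
                          hits$subject %in% pair_genes, , drop = FALSE]
      res <- tryCatch(
        gendiff_pair(genomes[[i]], genomes[[j]], hits = pair_hits,
                     mode = mode,
                     f_eps = f_eps, f_t = f_t, tau = tau, eps = eps,
                     config = config),
        error = function(e) e)
      timings[[key]] <- as.numeric(difftime(Sys.time(), t0,
                                            units = "secs"))
      if (inherits(res, "error")) {
        errors[[key]] <- conditionMessage(res)
        next
      }
      solutions[[key]] <- res$solution
      os <- res$solution$ortholog_set
      pairwise[[key]] <- data.frame(
        gene_a = os$a, genome_a = gn[i], gene_b = os$b, genome_b = gn[j],
        sigma = os$sigma, stringsAsFactors = FALSE)
    }
  }
  universe <- do.call(rbind, lapply(gn, function(g)
    data.frame(gene = gene_table(genomes[[g]])$gene, genome = g,
               stringsAsFactors = FALSE)))
  fg <- integrate_ortholog_sets(pairwise, genes = universe)
  fams_raw <- classify_families(fg, n = length(gn))
  fams <- if (mcl) refine_families(fams_raw, fg, inflation = inflation)
  else fams_raw
  fset <- as_family_set(fams, provenance = "pipeline")
  out <- structure(list(families = fams, families_raw = fams_raw,
                        family_set = fset, family_graph = fg,
                        solutions = solutions, errors = errors,
                        timings = timings, mode = mode),
                   class = "ffdcj_pipeline_result")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_families(fset, file.path(out_dir, "families.txt"))
    cls <- vapply(fams$families, `[[`, character(1), "class")
    writeLines(paste(vapply(fams$families, function(f)
      paste(f$genes, collapse = " "), character(1)), cls, sep = "\t"),
      file.path(out_dir, "families_classified.tsv"))
    for (key in names(solutions)) {
      safe <- gsub("[^A-Za-z0-9_.-]", "_", key)
      write_solution(solutions[[key]],
                     json_path = file.path(out_dir,
                                           paste0(safe, ".json")),
                     tsv_path = file.path(out_dir, paste0(safe, ".tsv")))
    }
    if (length(errors))
      writeLines(paste(names(errors), unlist(errors), sep = "\t"),
                 file.path(out_dir, "errors.tsv"))
  }
  if (length(errors))
    warning("pipeline finished with ", length(errors), " failed pair(s)")
  out
}

#' @export
print.ffdcj_pipeline_result <- function(x, ...) {
  cat("Pipeline result (", x$mode, " capping): ",
      length(x$solutions), " pairwise comparisons, ",
      length(x$errors), " failed\n", sep = "")
  print(x$families)
  invisible(x)
}

#' Load a worked-example fixture
#'
#' Small instances shipped with the package:
#' \describe{
#'   \item{`toy_pair`}{Two genomes of 6 and 7 genes (2 and 1 linear
#'     segments) with a small similarity graph; the classic worked example
#'     for decompositions and capping.  Similarity scores are a documented
#'     plausible assignment (structural properties, not the scores, are
#'     meaningful).}
#'   \item{`segment_graph`}{A 5+5-segment shared-content graph whose
#'     completion needs exactly one dummy segment per side and whose final
#'     pruned graph contains a non-complete bipartite component
#'     (synthetic construction).}
#'   \item{`translocation_pair`}{Two genomes of 9 identically-labelled
#'     genes differing by one translocation (distance 1 under the identity
#'     matching).}
#'   \item{`deletion_pair`}{A 6-gene and a 3-gene genome differing by one
#'     block deletion (distance 1 under the natural matching).}
#' }
#'
#' @param name One of the fixture names above.
#' @return A list of typed objects (genomes, similarity graph / content
#'   edges, suggested matching) depending on the fixture.
#' @export
load_fixture <- function(name = c("toy_pair", "segment_graph",
                                  "translocation_pair", "deletion_pair")) {
  name <- match.arg(name)
  path <- function(f) system.file("extdata", f, package = "ffdcj",
                                  mustWork = TRUE)
  switch(name,
    toy_pair = {
      A <- parse_gene_orders(path("toy_pair_A.txt"), genome_id = "A")
      B <- parse_gene_orders(path("toy_pair_B.txt"), genome_id = "B")
      ed <- utils::read.delim(path("toy_pair_similarity.tsv"),
                              colClasses = c("character", "character",
                                             "numeric"))
      S <- similarity_graph(A, B, ed)
      list(A = A, B = B, S = S,
           ortholog_set = cbind(c("1", "3", "4", "5"),
                                c("7", "10", "9", "13")))
    },
    segment_graph = {
      ed <- utils::read.delim(path("segment_graph_content.tsv"),
                              colClasses = c("character", "character",
                                             "numeric"))
      structure(list(seg_a = paste0("A", 1:5), seg_b = paste0("B", 1:5),
                     dummy_a = character(0), dummy_b = character(0),
                     edges = ed, tau = NA_integer_, eps = NA_real_,
                     perfect = FALSE),
                class = "ffdcj_scg")
    },
    translocation_pair = {
      A <- parse_gene_orders(path("translocation_A.txt"), genome_id = "A")
      B <- parse_gene_orders(path("translocation_B.txt"), genome_id = "B")
      g <- gene_table(A)$gene
      list(A = A, B = B, matching = cbind(g, g))
    },
    deletion_pair = {
      A <- parse_gene_orders(path("deletion_A.txt"), genome_id = "A")
      B <- parse_gene_orders(path("deletion_B.txt"), genome_id = "B")
      list(A = A, B = B,
           matching = cbind(c("3", "5", "4"), c("3", "5", "4")))
    })
}
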