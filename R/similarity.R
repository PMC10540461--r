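#' Relative reciprocal score of a gene pair
#'
#' Normalised similarity of genes x and y from their reciprocal bitscores:
#' `(b_xy + b_yx) / (b_xx + b_yy)`, clipped to at most 1 so that edge scores
#' and the vertex weights derived from them stay in (0, 1] (reciprocal
#' bitscores can arithmetically exceed self-scores).
#'
#' @param b_xy,b_yx Cross bitscores (x vs y and y vs x), positive.
#' @param b_xx,b_yy Self bitscores, positive.
#' @return Numeric score in (0, 1].  Vectorised.
#' @examples
#' relative_reciprocal_score(50, 50, 100, 100)  # 0.5
#' @export
relative_reciprocal_score <- function(b_xy, b_yx, b_xx, b_yy) {
  if (any(c(b_xx, b_yy) <= 0) || anyNA(c(b_xx, b_yy)))
    stop("self bitscores must be positive")
  if (any(c(b_xy, b_yx) <= 0) || anyNA(c(b_xy, b_yx)))
    stop("cross bitscores must be positive")
  pmin(1, (b_xy + b_yx) / (b_xx + b_yy))
}

#' Build the filtered gene similarity graph of two genomes
#'
#' Constructs the weighted bipartite gene similarity graph between the genes
#' of genomes `A` and `B` from a table of reciprocal bitscore hits.  An edge
#' xy with score `sigma = relative_reciprocal_score(...)` is kept iff
#' (1) `sigma >= f_eps` (absolute filter) and (2) `b_xy` is at least an
#' `f_t`-fraction of the best bitscore of x against any gene of `B`, and
#' `b_yx` at least an `f_t`-fraction of the best bitscore of y against any
#' gene of `A` (relative reciprocal filter; maxima over raw bitscores).
#' Genes with no surviving edge stay as isolated vertices with weight 0 —
#' they still occur in the gene orders and take part in indels.
#'
#' @param A,B `ffdcj_genome` objects.
#' @param hits A `ffdcj_hits` table (see [hits_table()]), containing both
#'   directions of every candidate cross hit and self hits for every gene
#'   involved in one.
#' @param f_eps Absolute similarity threshold in (0, 1], default 0.1.
#' @param f_t Relative reciprocal threshold in (0, 1], default 0.8.
#' @return An object of class `ffdcj_simgraph` with components `genes_a`,
#'   `genes_b`, `edges` (data.frame `a`, `b`, `sigma`), and named weight
#'   vectors `w_a`, `w_b`.
#' @export
build_similarity_graph <- function(A, B, hits, f_eps = 0.1, f_t = 0.8) {
  stopifnot(inherits(A, "ffdcj_genome"), inherits(B, "ffdcj_genome"))
  stopifnot(f_eps > 0, f_eps <= 1, f_t > 0, f_t <= 1)
  genes_a <- gene_table(A)$gene
  genes_b <- gene_table(B)$gene
  if (length(intersect(genes_a, genes_b)))
    stop("genomes share gene ids; ids must be distinct between genomes")
  w_a <- stats::setNames(numeric(length(genes_a)), genes_a)
  w_b <- stats::setNames(numeric(length(genes_b)), genes_b)
  empty <- data.frame(a = character(0), b = character(0), sigma = numeric(0),
                      stringsAsFactors = FALSE)
  res <- structure(list(genome_a = A$genome_id, genome_b = B$genome_id,
                        genes_a = genes_a, genes_b = genes_b,
                        edges = empty, w_a = w_a, w_b = w_b,
                        f_eps = f_eps, f_t = f_t),
                   class = "ffdcj_simgraph")
  if (is.null(hits) || nrow(hits) == 0L) return(res)

  in_a <- hits$query %in% genes_a | hits$subject %in% genes_a
  in_b <- hits$query %in% genes_b | hits$subject %in% genes_b
  unknown <- !(hits$query %in% c(genes_a, genes_b)) |
    !(hits$subject %in% c(genes_a, genes_b))
  self <- hits$query == hits$subject
  if (any(unknown & !self)) {
    warning(sum(unknown & !self),
            " hit(s) reference genes absent from both genomes; skipped")
  }
  score <- stats::setNames(hits$bitscore,
                           paste(hits$query, hits$subject, sep = "\r"))
  ab <- hits[hits$query %in% genes_a & hits$subject %in% genes_b, ,
             drop = FALSE]
  ba <- hits[hits$query %in% genes_b & hits$subject %in% genes_a, ,
             drop = FALSE]
  if (nrow(ab) == 0L) return(res)
  # best raw bitscore of each gene against the opposite genome
  best_a <- tapply(ab$bitscore, ab$query, max)
  best_b <- tapply(ba$bitscore, ba$query, max)
  # candidate pairs require both directions
  key_ab <- paste(ab$query, ab$subject, sep = "\r")
  key_ba_rev <- paste(ba$subject, ba$query, sep = "\r")
  cand <- ab[key_ab %in% key_ba_rev, , drop = FALSE]
  if (nrow(cand) == 0L) return(res)
  x <- cand$query
  y <- cand$subject
  b_xy <- cand$bitscore
  b_yx <- as.numeric(score[paste(y, x, sep = "\r")])
  b_xx <- as.numeric(score[paste(x, x, sep = "\r")])
  b_yy <- as.numeric(score[paste(y, y, sep = "\r")])
  if (anyNA(b_xx) || anyNA(b_yy)) {
    miss <- unique(c(x[is.na(b_xx)], y[is.na(b_yy)]))
    stop("missing self hit(s) for gene(s): ", paste(miss, collapse = ", "))
  }
  sigma <- relative_reciprocal_score(b_xy, b_yx, b_xx, b_yy)
  keep <- sigma >= f_eps &
    b_xy >= f_t * as.numeric(best_a[x]) &
    b_yx >= f_t * as.numeric(best_b[y])
  edges <- data.frame(a = x[keep], b = y[keep], sigma = sigma[keep],
                      stringsAsFactors = FALSE)
  edges <- edges[order(edges$a, edges$b), , drop = FALSE]
  rownames(edges) <- NULL
  res$edges <- edges
  if (nrow(edges)) {
    wa <- tapply(edges$sigma, edges$a, max)
    wb <- tapply(edges$sigma, edges$b, max)
    res$w_a[names(wa)] <- as.numeric(wa)
    res$w_b[names(wb)] <- as.numeric(wb)
  }
  res
}

#' Construct a gene similarity graph from an explicit edge list
#'
#' Low-level constructor used by fixtures and simulations where edge scores
#' are given directly rather than derived from bitscores.
#'
#' @param A,B `ffdcj_genome` objects.
#' @param edges data.frame with columns `a`, `b`, `sigma` (scores in (0, 1]).
#' @return An `ffdcj_simgraph`.
#' @export
similarity_graph <- function(A, B, edges) {
  stopifnot(inherits(A, "ffdcj_genome"), inherits(B, "ffdcj_genome"))
  genes_a <- gene_table(A)$gene
  genes_b <- gene_table(B)$gene
  edges <- data.frame(a = as.character(edges$a), b = as.character(edges$b),
                      sigma = as.numeric(edges$sigma),
                      stringsAsFactors = FALSE)
  if (any(!(edges$a %in% genes_a)) || any(!(edges$b %in% genes_b)))
    stop("edge endpoints must be genes of A (column a) and B (column b)")
  if (any(edges$sigma <= 0 | edges$sigma > 1))
    stop("sigma scores must be in (0, 1]")
  if (anyDuplicated(paste(edges$a, edges$b)))
    stop("duplicate similarity edges")
  w_a <- stats::setNames(numeric(length(genes_a)), genes_a)
  w_b <- stats::setNames(numeric(length(genes_b)), genes_b)
  if (nrow(edges)) {
    wa <- tapply(edges$sigma, edges$a, max)
    wb <- tapply(edges$sigma, edges$b, max)
    w_a[names(wa)] <- as.numeric(wa)
    w_b[names(wb)] <- as.numeric(wb)
  }
  edges <- edges[order(edges$a, edges$b), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(genome_a = A$genome_id, genome_b = B$genome_id,
                 genes_a = genes_a, genes_b = genes_b,
                 edges = edges, w_a = w_a, w_b = w_b,
                 f_eps = NA_real_, f_t = NA_real_),
            class = "ffdcj_simgraph")
}

#' @export
print.ffdcj_simgraph <- function(x, ...) {
  cat("Gene similarity graph ", x$genome_a, " vs ", x$genome_b, ": ",
      length(x$genes_a), "+", length(x$genes_b), " genes, ",
      nrow(x$edges), " edges\n", sep = "")
  invisible(x)
}

#' Dump a similarity graph as an edge list
#'
#' Writes `gene_a TAB gene_b TAB sigma` rows for inspection.
#'
#' @param S An `ffdcj_simgraph`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_similarity_edges <- function(S, path) {
  stopifnot(inherits(S, "ffdcj_simgraph"))
  writeLines(sprintf("%s\t%s\t%g", S$edges$a, S$edges$b, S$edges$sigma), path)
  invisible(path)
}
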