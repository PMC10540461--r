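# Integration of pairwise ortholog-sets into an n-partite family graph,
# family classification, Markov-clustering refinement of ambiguous
# families, and pair-based evaluation against reference families.

# simple union-find
uf_new <- function(n) seq_len(n)
uf_find <- function(parent, x) {
  while (parent[x] != x) x <- parent[x]
  x
}

#' Integrate pairwise ortholog-sets into a family graph
#'
#' Builds the n-partite graph whose vertices are the genes of all genomes
#' and whose edges are the union of the pairwise ortholog pairs (weighted
#' by their similarity scores).  Connected components are the inferred
#' gene families; genes appearing in no pair are reported as unclassified
#' singletons.
#'
#' @param pairwise List of data.frames with columns `gene_a`, `genome_a`,
#'   `gene_b`, `genome_b`, `sigma`; each must be a matching between two
#'   distinct genomes.
#' @param genes Optional data.frame (`gene`, `genome`) giving the full gene
#'   universe, so that matchless genes appear as singletons.
#' @return An object of class `ffdcj_family_graph`.
#' @export
integrate_ortholog_sets <- function(pairwise, genes = NULL) {
  stopifnot(is.list(pairwise))
  edges <- list()
  for (df in pairwise) {
    need <- c("gene_a", "genome_a", "gene_b", "genome_b", "sigma")
    if (!all(need %in% names(df)))
      stop("each pairwise ortholog-set needs columns: ",
           paste(need, collapse = ", "))
    if (nrow(df) == 0L) next
    if (length(unique(df$genome_a)) > 1L || length(unique(df$genome_b)) > 1L)
      stop("a pairwise ortholog-set must involve exactly two genomes")
    if (df$genome_a[1] == df$genome_b[1])
      stop("within-genome ortholog pairs are not allowed")
    if (anyDuplicated(df$gene_a) || anyDuplicated(df$gene_b))
      stop("a pairwise ortholog-set must be a matching")
    edges[[length(edges) + 1L]] <- df[need]
  }
  E <- if (length(edges)) do.call(rbind, edges) else
    data.frame(gene_a = character(0), genome_a = character(0),
               gene_b = character(0), genome_b = character(0),
               sigma = numeric(0))
  V <- rbind(
    data.frame(gene = E$gene_a, genome = E$genome_a,
               stringsAsFactors = FALSE),
    data.frame(gene = E$gene_b, genome = E$genome_b,
               stringsAsFactors = FALSE),
    if (!is.null(genes)) data.frame(gene = as.character(genes$gene),
                                    genome = as.character(genes$genome),
                                    stringsAsFactors = FALSE)
  )
  V <- V[!duplicated(V$gene), , drop = FALSE]
  rownames(V) <- NULL
  chk <- tapply(V$genome, V$gene, function(x) length(unique(x)))
  if (any(chk > 1L))
    stop("gene id(s) appear in more than one genome: ",
         paste(names(chk)[chk > 1L], collapse = ", "))
  idx <- stats::setNames(seq_len(nrow(V)), V$gene)
  parent <- uf_new(nrow(V))
  if (nrow(E)) {
    for (k in seq_len(nrow(E))) {
      ra <- uf_find(parent, idx[[E$gene_a[k]]])
      rb <- uf_find(parent, idx[[E$gene_b[k]]])
      if (ra != rb) parent[rb] <- ra
    }
  }
  comp <- vapply(seq_len(nrow(V)), function(i) uf_find(parent, i),
                 integer(1))
  structure(list(vertices = V, edges = E,
                 component = match(comp, unique(comp))),
            class = "ffdcj_family_graph")
}

#' @export
print.ffdcj_family_graph <- function(x, ...) {
  cat("Family graph: ", nrow(x$vertices), " genes from ",
      length(unique(x$vertices$genome)), " genomes, ",
      nrow(x$edges), " ortholog pairs, ",
      length(unique(x$component)), " components\n", sep = "")
  invisible(x)
}

classify_component <- function(genomes_of_genes, n_genomes) {
  tab <- table(genomes_of_genes)
  if (any(tab > 1L)) "ambiguous"
  else if (length(tab) == n_genomes) "resolved-complete"
  else "resolved-incomplete"
}

#' Classify the families of a family graph
#'
#' Every connected component with at least two genes is one family:
#' ambiguous if some genome contributes two or more genes, resolved-complete
#' if it has exactly one gene from each of the `n` genomes, and
#' resolved-incomplete otherwise.  Singleton components are reported as
#' unclassified genes, not families.
#'
#' @param fg An `ffdcj_family_graph`.
#' @param n Number of genomes (default: number observed in the graph).
#' @return An object of class `ffdcj_families`: list of families (each with
#'   `genes` and `class`), plus `unclassified` singleton genes.
#' @export
classify_families <- function(fg, n = NULL) {
  stopifnot(inherits(fg, "ffdcj_family_graph"))
  if (is.null(n)) n <- length(unique(fg$vertices$genome))
  comps <- split(seq_len(nrow(fg$vertices)), fg$component)
  fams <- list()
  unclassified <- character(0)
  for (cp in comps) {
    if (length(cp) == 1L) {
      unclassified <- c(unclassified, fg$vertices$gene[cp])
      next
    }
    genes <- sort(fg$vertices$gene[cp])
    fams[[length(fams) + 1L]] <-
      list(genes = genes,
           class = classify_component(fg$vertices$genome[cp], n))
  }
  structure(list(families = fams, n_genomes = n,
                 unclassified = sort(unclassified)),
            class = "ffdcj_families")
}

#' @export
print.ffdcj_families <- function(x, ...) {
  cls <- vapply(x$families, `[[`, character(1), "class")
  cat("Classified families (", x$n_genomes, " genomes):\n",
      "  resolved-complete:   ", sum(cls == "resolved-complete"), "\n",
      "  resolved-incomplete: ", sum(cls == "resolved-incomplete"), "\n",
      "  ambiguous:           ", sum(cls == "ambiguous"), "\n",
      "  unclassified genes:  ", length(x$unclassified), "\n", sep = "")
  invisible(x)
}

#' Markov clustering of a weighted graph
#'
#' Plain MCL: column-normalise the (self-looped) transition matrix, then
#' alternate expansion (matrix power) and inflation (elementwise power with
#' renormalisation), pruning negligible entries, until the matrix is stable.
#' Clusters are read from the attractor rows.
#'
#' @param adj Symmetric non-negative weight matrix with dimnames; diagonal
#'   may be zero (self-loops are added as the maximum incident weight).
#' @param inflation Inflation exponent (granularity), default 1.4.
#' @param expansion Expansion power, default 2.
#' @param prune Entries below this are dropped each iteration.
#' @param max_iter Iteration cap.
#' @return List of character vectors (clusters, covering all nodes).
#' @export
mcl_cluster <- function(adj, inflation = 1.4, expansion = 2L,
                        prune = 1e-5, max_iter = 100L) {
  stopifnot(is.matrix(adj), nrow(adj) == ncol(adj),
            !is.null(rownames(adj)))
  n <- nrow(adj)
  if (n == 1L) return(list(rownames(adj)))
  M <- adj
  diag(M) <- apply(adj, 1, max)  # self-loops
  M <- sweep(M, 2, pmax(colSums(M), .Machine$double.eps), "/")
  for (it in seq_len(max_iter)) {
    Mexp <- M
    for (k in seq_len(expansion - 1L)) Mexp <- Mexp %*% M
    Minf <- Mexp^inflation
    Minf[Minf < prune] <- 0
    cs <- colSums(Minf)
    cs[cs == 0] <- 1
    Minf <- sweep(Minf, 2, cs, "/")
    if (max(abs(Minf - M)) < 1e-8) { M <- Minf; break }
    M <- Minf
  }
  attractors <- which(diag(M) > 1e-6)
  clusters <- list()
  assigned <- rep(FALSE, n)
  for (a in attractors) {
    members <- which(M[a, ] > 1e-6)
    members <- members[!assigned[members]]
    if (!length(members)) next
    # merge with an existing cluster when attractor rows overlap
    hit <- which(vapply(clusters, function(cl)
      any(rownames(adj)[which(M[a, ] > 1e-6)] %in% cl), logical(1)))
    if (length(hit)) {
      clusters[[hit[1]]] <- union(clusters[[hit[1]]],
                                  rownames(adj)[members])
    } else {
      clusters[[length(clusters) + 1L]] <- rownames(adj)[members]
    }
    assigned[members] <- TRUE
  }
  # any node not claimed by an attractor row joins its strongest column
  for (v in which(!assigned)) {
    target <- which.max(M[, v])
    placed <- FALSE
    for (ci in seq_along(clusters)) {
      if (rownames(adj)[target] %in% clusters[[ci]]) {
        clusters[[ci]] <- c(clusters[[ci]], rownames(adj)[v])
        placed <- TRUE
        break
      }
    }
    if (!placed) clusters[[length(clusters) + 1L]] <- rownames(adj)[v]
    assigned[v] <- TRUE
  }
  lapply(clusters, sort)
}

#' Refine one ambiguous family by Markov clustering
#'
#' Applies [mcl_cluster()] to the similarity-weighted subgraph of an
#' ambiguous family and re-classifies the resulting clusters.  Families
#' that are not ambiguous are returned unchanged with a warning.
#'
#' @param family A family element (list with `genes` and `class`) as
#'   produced by [classify_families()].
#' @param edges data.frame (`gene_a`, `gene_b`, `sigma`) with the ortholog
#'   pairs inside the family.
#' @param n_genomes Number of genomes (for re-classification).
#' @param genome_of Named character vector mapping gene to genome.
#' @param inflation Inflation parameter, default 1.4.
#' @return List of family elements covering exactly the input genes.
#' @export
mcl_refine <- function(family, edges, n_genomes, genome_of,
                       inflation = 1.4) {
  if (family$class != "ambiguous") {
    warning("family is not ambiguous; returned unchanged")
    return(list(family))
  }
  genes <- family$genes
  adj <- matrix(0, length(genes), length(genes),
                dimnames = list(genes, genes))
  for (k in seq_len(nrow(edges))) {
    a <- edges$gene_a[k]; b <- edges$gene_b[k]
    if (a %in% genes && b %in% genes) {
      adj[a, b] <- max(adj[a, b], edges$sigma[k])
      adj[b, a] <- adj[a, b]
    }
  }
  clusters <- mcl_cluster(adj, inflation = inflation)
  lapply(clusters, function(cl)
    list(genes = sort(cl),
         class = if (length(cl) == 1L) "unclassified"
         else classify_component(unname(genome_of[cl]), n_genomes)))
}

#' Refine all ambiguous families of a classification
#'
#' @param fams An `ffdcj_families`.
#' @param fg The `ffdcj_family_graph` the classification came from.
#' @param inflation Inflation parameter, default 1.4.
#' @return A new `ffdcj_families`; genes are conserved, and the refined
#'   pair sets are subsets of the original ones.
#' @export
refine_families <- function(fams, fg, inflation = 1.4) {
  stopifnot(inherits(fams, "ffdcj_families"),
            inherits(fg, "ffdcj_family_graph"))
  genome_of <- stats::setNames(fg$vertices$genome, fg$vertices$gene)
  out <- list()
  unclassified <- fams$unclassified
  for (f in fams$families) {
    if (f$class != "ambiguous") {
      out[[length(out) + 1L]] <- f
      next
    }
    parts <- mcl_refine(f, fg$edges, fams$n_genomes, genome_of,
                        inflation = inflation)
    for (p in parts) {
      if (p$class == "unclassified")
        unclassified <- c(unclassified, p$genes)
      else out[[length(out) + 1L]] <- p
    }
  }
  structure(list(families = out, n_genomes = fams$n_genomes,
                 unclassified = sort(unclassified)),
            class = "ffdcj_families")
}

#' Convert classified families to a plain family set
#'
#' @param fams An `ffdcj_families`.
#' @param provenance Label for the family set.
#' @param include_unclassified Include singleton genes as singleton
#'   families (default `FALSE`).
#' @return An `ffdcj_family_set`.
#' @export
as_family_set <- function(fams, provenance = "inferred",
                          include_unclassified = FALSE) {
  stopifnot(inherits(fams, "ffdcj_families"))
  fl <- lapply(fams$families, `[[`, "genes")
  if (include_unclassified)
    fl <- c(fl, as.list(fams$unclassified))
  family_set(fl, provenance = provenance)
}

pair_keys <- function(fs) {
  out <- character(0)
  for (f in fs$families) {
    if (length(f) < 2L) next
    cmb <- utils::combn(sort(f), 2L)
    out <- c(out, paste(cmb[1, ], cmb[2, ], sep = "\r"))
  }
  unique(out)
}

#' Pairwise homology metrics of a family set against a reference
#'
#' Compares the 2-subsets (unordered within-family gene pairs) of an
#' inferred family set `X` against those of a reference: TP are the common
#' pairs, FP the pairs only in `X`, FN the pairs only in the reference;
#' precision = TP/(TP+FP), recall = TP/(TP+FN), F1 their harmonic mean.
#' Genes absent from the reference are filtered out of `X` first, so the
#' inferred set is judged only on genes the reference classifies.
#' Degenerate cases (no pairs at all on one side) report 0 with a flag.
#'
#' @param X,ref `ffdcj_family_set` objects.
#' @return An object of class `ffdcj_metrics` with fields `tp`, `fp`, `fn`,
#'   `precision`, `recall`, `f1`, `degenerate`.
#' @export
homology_pair_metrics <- function(X, ref) {
  stopifnot(inherits(X, "ffdcj_family_set"),
            inherits(ref, "ffdcj_family_set"))
  genes_r <- unlist(ref$families, use.names = FALSE)
  restricted_x <- lapply(X$families, function(f) intersect(f, genes_r))
  hx <- pair_keys(list(families = restricted_x[lengths(restricted_x) > 0L]))
  hr <- pair_keys(ref)
  tp <- length(intersect(hx, hr))
  fp <- length(setdiff(hx, hr))
  fn <- length(setdiff(hr, hx))
  degenerate <- length(hx) == 0L || length(hr) == 0L
  precision <- if (tp + fp > 0L) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0L) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0) 2 * precision * recall /
    (precision + recall) else 0
  structure(list(tp = tp, fp = fp, fn = fn, precision = precision,
                 recall = recall, f1 = f1, degenerate = degenerate),
            class = "ffdcj_metrics")
}

#' @export
print.ffdcj_metrics <- function(x, ...) {
  cat("Pairwise homology metrics\n",
      "  TP = ", x$tp, ", FP = ", x$fp, ", FN = ", x$fn, "\n",
      "  precision = ", format(x$precision, digits = 4),
      ", recall = ", format(x$recall, digits = 4),
      ", F1 = ", format(x$f1, digits = 4),
      if (x$degenerate) "  [degenerate: no pairs on one side]" else "",
      "\n", sep = "")
  invisible(x)
}
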