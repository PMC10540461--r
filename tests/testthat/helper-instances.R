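# Shared builders for tiny test instances.

g_str <- function(id, text) genome_from_string(id, text)

# similarity graph from triples "a b sigma"
sim_from <- function(A, B, ...) {
  tr <- list(...)
  if (length(tr)) {
    m <- do.call(rbind, tr)
    edges <- data.frame(a = as.character(m[, 1]), b = as.character(m[, 2]),
                        sigma = as.numeric(m[, 3]),
                        stringsAsFactors = FALSE)
  } else {
    edges <- data.frame(a = character(0), b = character(0),
                        sigma = numeric(0))
  }
  similarity_graph(A, B, edges)
}

# ortholog pairs from an ffr sibling-set (edge indices)
pairs_of_L <- function(ffr, L) {
  data.frame(a = ffr$gene_a[ffr$sim$ai[L]],
             b = ffr$gene_b[ffr$sim$bi[L]], stringsAsFactors = FALSE)
}

# brute-force perfect matching enumeration on a biadjacency matrix
all_perfect_matchings <- function(adj) {
  n <- nrow(adj)
  if (n != ncol(adj)) return(list())
  out <- list()
  recurse <- function(row, used, acc) {
    if (row > n) {
      out[[length(out) + 1L]] <<- acc
      return(invisible(NULL))
    }
    for (col in seq_len(n)) {
      if (!used[col] && adj[row, col]) {
        used[col] <- TRUE
        recurse(row + 1L, used, c(acc, col))
        used[col] <- FALSE
      }
    }
    invisible(NULL)
  }
  recurse(1L, logical(n), integer(0))
  out
}

# a shared-content graph object built directly from parts (tests only)
scg_from <- function(seg_a, seg_b, edges, dummy_a = character(0),
                     dummy_b = character(0), perfect = FALSE) {
  structure(list(seg_a = seg_a, seg_b = seg_b, dummy_a = dummy_a,
                 dummy_b = dummy_b, edges = edges, tau = NA_integer_,
                 eps = NA_real_, perfect = perfect),
            class = "ffdcj_scg")
}
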