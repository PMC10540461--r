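# Seeded synthetic data: an ancestral genome evolved per lineage by DCJ
# rearrangements (inversions/translocations, keeping segments linear),
# block deletions, insertions of novel genes and tandem-free duplications,
# with bitscore tables emitted so that planted orthologs pass the
# similarity filters and noise hits are controllable.

#' Specification for synthetic genome evolution
#'
#' @param n_genomes Number of genomes (>= 2).
#' @param n_genes Ancestral gene count.
#' @param n_segments Linear segments of the ancestor (kept constant along
#'   each lineage).
#' @param n_dcj Random DCJ rearrangements per lineage (inversions and, with
#'   several segments, translocations).
#' @param n_del Block deletions per lineage (blocks of up to `del_len`
#'   genes; a lineage never empties a segment).
#' @param n_ins Insertions of novel lineage-specific genes per lineage.
#' @param dup_rate Per-gene duplication probability (creates ambiguous
#'   similarity).
#' @param noise Per-cross-genome-gene-pair probability of a spurious weak
#'   hit.
#' @param del_len Maximum deletion block length, default 2.
#' @param seed Integer seed fixing all randomness.
#' @return A list of class `ffdcj_synth_spec`.
#' @export
synthetic_spec <- function(n_genomes = 3L, n_genes = 12L, n_segments = 2L,
                           n_dcj = 3L, n_del = 0L, n_ins = 0L,
                           dup_rate = 0, noise = 0, del_len = 2L,
                           seed = 1L) {
  stopifnot(n_genomes >= 2L, n_genes >= n_segments, n_segments >= 1L,
            n_dcj >= 0L, n_del >= 0L, n_ins >= 0L,
            dup_rate >= 0, dup_rate <= 1, noise >= 0, noise <= 1)
  if (n_genes - n_del * del_len < n_segments)
    stop("deletions could empty the genome; reduce n_del")
  structure(as.list(environment()), class = "ffdcj_synth_spec")
}

random_inversion <- function(seg) {
  n <- length(seg$genes)
  if (n < 1L) return(seg)
  i <- sample.int(n, 1L)
  j <- sample.int(n, 1L)
  if (i > j) { t <- i; i <- j; j <- t }
  idx <- i:j
  seg$genes[idx] <- rev(seg$genes[idx])
  seg$orient[idx] <- -rev(seg$orient[idx])
  seg
}

# translocation: exchange suffixes of two segments (possibly empty)
random_translocation <- function(s1, s2) {
  c1 <- sample.int(length(s1$genes) + 1L, 1L) - 1L  # keep first c1 genes
  c2 <- sample.int(length(s2$genes) + 1L, 1L) - 1L
  head1 <- list(genes = s1$genes[seq_len(c1)], orient = s1$orient[seq_len(c1)])
  tail1 <- list(genes = s1$genes[setdiff(seq_along(s1$genes), seq_len(c1))],
                orient = s1$orient[setdiff(seq_along(s1$genes), seq_len(c1))])
  head2 <- list(genes = s2$genes[seq_len(c2)], orient = s2$orient[seq_len(c2)])
  tail2 <- list(genes = s2$genes[setdiff(seq_along(s2$genes), seq_len(c2))],
                orient = s2$orient[setdiff(seq_along(s2$genes), seq_len(c2))])
  n1 <- list(genes = c(head1$genes, tail2$genes),
             orient = c(head1$orient, tail2$orient))
  n2 <- list(genes = c(head2$genes, tail1$genes),
             orient = c(head2$orient, tail1$orient))
  if (!length(n1$genes) || !length(n2$genes)) return(list(s1, s2))
  list(n1, n2)
}

#' Generate a synthetic dataset with planted orthologies
#'
#' Evolves an ancestral genome independently along each lineage according
#' to the spec, and emits (a) the genomes, (b) an all-vs-all bitscore table
#' (self hits included) in which planted orthologs/paralogs score high
#' enough to pass the default similarity filters, and (c) the planted
#' families (all extant copies of each ancestral gene present in at least
#' two genomes).
#'
#' @param spec An [synthetic_spec()].
#' @return List with `genomes` (named list of `ffdcj_genome`), `hits`
#'   (`ffdcj_hits`), `families` (`ffdcj_family_set`), `origin` (named
#'   vector: ancestral origin of every gene; novel genes are `NA`).
#' @export
generate_synthetic_dataset <- function(spec) {
  stopifnot(inherits(spec, "ffdcj_synth_spec"))
  set.seed(spec$seed)
  # ancestor: genes 1..n_genes split into segments
  cuts <- sort(sample.int(spec$n_genes - 1L, spec$n_segments - 1L))
  bounds <- c(0L, cuts, spec$n_genes)
  genomes <- list()
  origin <- character(0)
  for (gi in seq_len(spec$n_genomes)) {
    gid <- paste0("G", gi)
    counter <- 0L
    segs <- list()
    for (si in seq_len(spec$n_segments)) {
      anc <- (bounds[si] + 1L):bounds[si + 1L]
      ids <- character(length(anc))
      for (k in seq_along(anc)) {
        counter <- counter + 1L
        ids[k] <- sprintf("%s_g%03d", gid, counter)
        origin[ids[k]] <- as.character(anc[k])
      }
      segs[[paste0("s", si)]] <- list(genes = ids,
                                      orient = rep(1L, length(ids)))
    }
    # deletions (avoid emptying a segment)
    for (k in seq_len(spec$n_del)) {
      cand <- which(vapply(segs, function(s) length(s$genes) > 1L,
                           logical(1)))
      if (!length(cand)) break
      si <- cand[sample.int(length(cand), 1L)]
      s <- segs[[si]]
      len <- min(sample.int(spec$del_len, 1L), length(s$genes) - 1L)
      i <- sample.int(length(s$genes) - len + 1L, 1L)
      drop <- i:(i + len - 1L)
      segs[[si]] <- list(genes = s$genes[-drop], orient = s$orient[-drop])
    }
    # duplications
    all_ids <- unlist(lapply(segs, `[[`, "genes"), use.names = FALSE)
    for (g in all_ids) {
      if (stats::runif(1) < spec$dup_rate) {
        counter <- counter + 1L
        nid <- sprintf("%s_g%03d", gid, counter)
        origin[nid] <- origin[[g]]
        si <- sample.int(length(segs), 1L)
        pos <- sample.int(length(segs[[si]]$genes) + 1L, 1L) - 1L
        segs[[si]]$genes <- append(segs[[si]]$genes, nid, after = pos)
        segs[[si]]$orient <- append(segs[[si]]$orient,
                                    sample(c(-1L, 1L), 1L), after = pos)
      }
    }
    # insertions of novel genes
    for (k in seq_len(spec$n_ins)) {
      counter <- counter + 1L
      nid <- sprintf("%s_g%03d", gid, counter)
      origin[nid] <- NA_character_
      si <- sample.int(length(segs), 1L)
      pos <- sample.int(length(segs[[si]]$genes) + 1L, 1L) - 1L
      segs[[si]]$genes <- append(segs[[si]]$genes, nid, after = pos)
      segs[[si]]$orient <- append(segs[[si]]$orient,
                                  sample(c(-1L, 1L), 1L), after = pos)
    }
    # rearrangements
    for (k in seq_len(spec$n_dcj)) {
      if (length(segs) >= 2L && stats::runif(1) < 0.4) {
        ij <- sample.int(length(segs), 2L)
        tr <- random_translocation(segs[[ij[1]]], segs[[ij[2]]])
        segs[[ij[1]]] <- tr[[1]]
        segs[[ij[2]]] <- tr[[2]]
      } else {
        si <- sample.int(length(segs), 1L)
        segs[[si]] <- random_inversion(segs[[si]])
      }
    }
    genomes[[gid]] <- genome(gid, segs)
  }
  # bitscore table
  q <- character(0); s <- character(0); b <- numeric(0)
  all_genes <- lapply(genomes, function(g) gene_table(g)$gene)
  for (gid in names(genomes)) {
    ids <- all_genes[[gid]]
    q <- c(q, ids); s <- c(s, ids); b <- c(b, rep(200, length(ids)))
  }
  gn <- names(genomes)
  for (i in seq_along(gn)) {
    for (j in seq_along(gn)) {
      if (i == j) next
      gi <- all_genes[[gn[i]]]
      gj <- all_genes[[gn[j]]]
      oi <- origin[gi]
      oj <- origin[gj]
      for (x in seq_along(gi)) {
        same <- which(!is.na(oj) & !is.na(oi[x]) & oj == oi[x])
        for (y in same) {
          q <- c(q, gi[x]); s <- c(s, gj[y])
          b <- c(b, 190 - 2 * (y %% 3))
        }
        if (spec$noise > 0) {
          nz <- which(stats::runif(length(gj)) < spec$noise)
          nz <- setdiff(nz, same)
          for (y in nz) {
            q <- c(q, gi[x]); s <- c(s, gj[y])
            b <- c(b, stats::runif(1, 30, 60))
          }
        }
      }
    }
  }
  hits <- hits_table(q, s, b)
  # planted families: extant copies per ancestral origin, over >= 2 genomes
  fam_split <- split(names(origin)[!is.na(origin)],
                     origin[!is.na(origin)])
  genome_of <- sub("_g[0-9]+$", "", names(origin))
  names(genome_of) <- names(origin)
  fams <- Filter(function(f) length(unique(genome_of[f])) >= 2L, fam_split)
  list(genomes = genomes, hits = hits,
       families = family_set(unname(fams), provenance = "planted"),
       origin = origin)
}

#' Random tiny relational-graph instance
#'
#' Seeded generator of small genome pairs with a random similarity graph,
#' used for exhaustive validation of the capping and distance machinery
#' (consistent decompositions, capping-set enumeration, solver oracles).
#'
#' @param seed Integer seed.
#' @param max_genes Maximum genes per genome (>= 1), default 4.
#' @param max_segments Maximum linear segments per genome, default 3.
#' @param edge_prob Probability of a similarity edge between any cross pair,
#'   default 0.35.
#' @return List with `A`, `B` (`ffdcj_genome`), `S` (`ffdcj_simgraph`) and
#'   `ffr` (`ffdcj_ffr`).
#' @export
random_ffr_instance <- function(seed, max_genes = 4L, max_segments = 3L,
                                edge_prob = 0.35) {
  set.seed(seed)
  mk <- function(prefix) {
    n <- sample.int(max_genes, 1L)
    k <- sample.int(min(max_segments, n), 1L)
    ids <- paste0(prefix, seq_len(n))
    orient <- sample(c(-1L, 1L), n, replace = TRUE)
    cuts <- if (k > 1L) sort(sample.int(n - 1L, k - 1L)) else integer(0)
    bounds <- c(0L, cuts, n)
    segs <- list()
    for (si in seq_len(k)) {
      idx <- (bounds[si] + 1L):bounds[si + 1L]
      segs[[paste0(prefix, "s", si)]] <- list(genes = ids[idx],
                                              orient = orient[idx])
    }
    genome(prefix, segs)
  }
  A <- mk("a")
  B <- mk("b")
  ga <- gene_table(A)$gene
  gb <- gene_table(B)$gene
  pairs <- expand.grid(a = ga, b = gb, stringsAsFactors = FALSE)
  keep <- stats::runif(nrow(pairs)) < edge_prob
  edges <- pairs[keep, , drop = FALSE]
  edges$sigma <- round(stats::runif(nrow(edges), 0.2, 1), 2)
  S <- similarity_graph(A, B, edges)
  list(A = A, B = B, S = S, ffr = build_ffr(A, B, S))
}
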