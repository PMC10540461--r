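# Breadth-first state-space oracle for the DCJ-indel distance on tiny
# instances.  Explores all genomes reachable by DCJ operations (including
# circular intermediates) and by insertions/deletions of contiguous blocks,
# under the no-reinsertion restriction: only genes of A unmatched by the
# ortholog-set may be deleted, only unmatched genes of B may be inserted,
# and each at most once.  Ground truth for the capped cycle/run formula.

chrom_canonical <- function(genes, circ) {
  if (!circ) {
    f <- paste(genes, collapse = ",")
    b <- paste(-rev(genes), collapse = ",")
    if (f <= b) f else b
  } else {
    n <- length(genes)
    best <- NULL
    for (dir in list(genes, -rev(genes))) {
      for (r in seq_len(n)) {
        rot <- c(dir[r:n], if (r > 1) dir[1:(r - 1)])
        s <- paste(rot, collapse = ",")
        if (is.null(best) || s < best) best <- s
      }
    }
    paste0("(", best, ")")
  }
}

state_key <- function(chroms) {
  if (!length(chroms)) return("-")
  paste(sort(vapply(chroms, function(c) chrom_canonical(c$genes, c$circ),
                    character(1))), collapse = "|")
}

# genome (integer-coded chromosomes) -> adjacency/telomere point set
chroms_to_points <- function(chroms) {
  pts <- list()
  for (ch in chroms) {
    g <- ch$genes
    n <- length(g)
    left <- ifelse(g > 0, 2L * abs(g) - 1L, 2L * abs(g))   # tail/head
    right <- ifelse(g > 0, 2L * abs(g), 2L * abs(g) - 1L)
    if (n > 1) {
      for (k in seq_len(n - 1))
        pts[[length(pts) + 1L]] <- c(right[k], left[k + 1L])
    }
    if (ch$circ) {
      pts[[length(pts) + 1L]] <- c(right[n], left[1L])
    } else {
      pts[[length(pts) + 1L]] <- left[1L]
      pts[[length(pts) + 1L]] <- right[n]
    }
  }
  pts
}

points_to_chroms <- function(pts) {
  nbr <- new.env(hash = TRUE)
  tel <- integer(0)
  exts <- integer(0)
  for (p in pts) {
    if (length(p) == 2L) {
      assign(as.character(p[1]), p[2], envir = nbr)
      assign(as.character(p[2]), p[1], envir = nbr)
      exts <- c(exts, p)
    } else {
      tel <- c(tel, p)
      exts <- c(exts, p)
    }
  }
  other_ext <- function(e) if (e %% 2L == 1L) e + 1L else e - 1L
  gene_of <- function(e) (e + 1L) %/% 2L
  seen <- new.env(hash = TRUE)
  chroms <- list()
  walk <- function(start, circ) {
    genes <- integer(0)
    e <- start
    repeat {
      assign(as.character(e), TRUE, envir = seen)
      g <- gene_of(e)
      # entering at tail (odd) means forward
      genes <- c(genes, if (e %% 2L == 1L) g else -g)
      e2 <- other_ext(e)
      assign(as.character(e2), TRUE, envir = seen)
      nxt <- mget(as.character(e2), envir = nbr, ifnotfound = list(NULL))[[1]]
      if (is.null(nxt)) break
      if (circ && nxt == start) break
      e <- nxt
    }
    genes
  }
  for (t in tel) {
    if (exists(as.character(t), envir = seen)) next
    chroms[[length(chroms) + 1L]] <- list(genes = walk(t, FALSE),
                                          circ = FALSE)
  }
  for (e in unique(exts)) {
    if (exists(as.character(e), envir = seen)) next
    chroms[[length(chroms) + 1L]] <- list(genes = walk(e, TRUE), circ = TRUE)
  }
  chroms
}

dcj_successors <- function(chroms) {
  pts <- chroms_to_points(chroms)
  out <- list()
  np <- length(pts)
  add <- function(newpts) out[[length(out) + 1L]] <<- points_to_chroms(newpts)
  if (np >= 2L) {
    for (i in seq_len(np - 1L)) {
      for (j in (i + 1L):np) {
        P <- pts[[i]]; Q <- pts[[j]]
        rest <- pts[-c(i, j)]
        if (length(P) == 2L && length(Q) == 2L) {
          add(c(rest, list(c(P[1], Q[1]), c(P[2], Q[2]))))
          add(c(rest, list(c(P[1], Q[2]), c(P[2], Q[1]))))
        } else if (length(P) == 2L && length(Q) == 1L) {
          add(c(rest, list(c(P[1], Q[1]), P[2])))
          add(c(rest, list(c(P[2], Q[1]), P[1])))
        } else if (length(P) == 1L && length(Q) == 2L) {
          add(c(rest, list(c(Q[1], P[1]), Q[2])))
          add(c(rest, list(c(Q[2], P[1]), Q[1])))
        } else {
          add(c(rest, list(c(P[1], Q[1]))))
        }
      }
    }
  }
  # single adjacency cut into two telomeres
  for (i in seq_len(np)) {
    P <- pts[[i]]
    if (length(P) == 2L)
      add(c(pts[-i], list(P[1], P[2])))
  }
  out
}

indel_successors <- function(chroms, deletable, remaining_ins) {
  out <- list()
  # deletions: contiguous blocks made only of deletable genes
  for (ci in seq_along(chroms)) {
    ch <- chroms[[ci]]
    g <- ch$genes
    n <- length(g)
    ok <- abs(g) %in% deletable
    if (!ch$circ) {
      for (i in seq_len(n)) {
        if (!ok[i]) next
        j <- i
        while (j <= n && ok[j]) {
          keep <- g[-(i:j)]
          rest <- chroms[-ci]
          if (length(keep))
            rest[[length(rest) + 1L]] <- list(genes = keep, circ = FALSE)
          out[[length(out) + 1L]] <- rest
          j <- j + 1L
        }
      }
    } else {
      if (all(ok)) out[[length(out) + 1L]] <- chroms[-ci]
      for (i in seq_len(n)) {
        j <- i
        while (j < i + n - 1L) {
          idx <- ((i:j) - 1L) %% n + 1L
          if (!all(ok[idx])) break
          keep <- g[-idx]
          rest <- chroms[-ci]
          rest[[length(rest) + 1L]] <- list(genes = keep, circ = TRUE)
          out[[length(out) + 1L]] <- rest
          j <- j + 1L
        }
      }
    }
  }
  # insertions: any arrangement of any subset of remaining genes, as a
  # contiguous block anywhere, or as a new chromosome
  if (length(remaining_ins)) {
    subsets <- unlist(lapply(seq_along(remaining_ins), function(k)
      lapply(utils::combn(seq_along(remaining_ins), k, simplify = FALSE),
             function(ii) remaining_ins[ii])), recursive = FALSE)
    blocks <- list()
    for (sub in subsets) {
      perms <- permutations_of(sub)
      for (pm in perms) {
        signs <- sign_patterns(length(pm))
        for (sg in signs)
          blocks[[length(blocks) + 1L]] <- pm * sg
      }
    }
    for (blk in blocks) {
      out[[length(out) + 1L]] <- c(chroms, list(list(genes = blk,
                                                     circ = FALSE)))
      out[[length(out) + 1L]] <- c(chroms, list(list(genes = blk,
                                                     circ = TRUE)))
      for (ci in seq_along(chroms)) {
        ch <- chroms[[ci]]
        n <- length(ch$genes)
        positions <- if (ch$circ) seq_len(n) else 0:n
        for (pos in positions) {
          g <- append(ch$genes, blk, after = pos)
          rest <- chroms
          rest[[ci]] <- list(genes = g, circ = ch$circ)
          out[[length(out) + 1L]] <- rest
        }
      }
    }
  }
  out
}

permutations_of <- function(x) {
  if (length(x) <= 1L) return(list(x))
  out <- list()
  for (i in seq_along(x))
    for (rest in permutations_of(x[-i]))
      out[[length(out) + 1L]] <- c(x[i], rest)
  out
}

sign_patterns <- function(n) {
  if (n == 0L) return(list(integer(0)))
  out <- list()
  for (bits in 0:(2^n - 1)) {
    s <- ifelse(bitwAnd(bits, 2^(seq_len(n) - 1L)) > 0, -1L, 1L)
    out[[length(out) + 1L]] <- s
  }
  out
}

#' DCJ-indel distance by exhaustive breadth-first search (oracle)
#'
#' Independent ground truth for [dcj_indel_distance()] on tiny instances:
#' explores the genome state space under all DCJ operations (circular
#' intermediates allowed) and all block insertions/deletions respecting the
#' no-reinsertion restriction, and returns the length of the shortest
#' operation sequence transforming `A` into `B` under the ortholog-set `O`.
#'
#' @param A,B `ffdcj_genome` objects (small: a handful of genes).
#' @param O Ortholog-set as in [dcj_indel_distance()].
#' @param max_states Guard on explored states (default 2e5).
#' @param max_depth Guard on search depth (default 12).
#' @return Integer operation count.
#' @export
dcj_indel_distance_bfs <- function(A, B, O, max_states = 2e5,
                                   max_depth = 12L) {
  m <- as_ortholog_pairs(O)
  ta <- gene_table(A)
  tb <- gene_table(B)
  if (nrow(m)) {
    swap <- !(m[, 1] %in% ta$gene & m[, 2] %in% tb$gene) &
      (m[, 1] %in% tb$gene & m[, 2] %in% ta$gene)
    m[swap, ] <- m[swap, c(2, 1)]
  }
  code <- integer(0)
  codes_a <- stats::setNames(rep(NA_integer_, nrow(ta)), ta$gene)
  codes_b <- stats::setNames(rep(NA_integer_, nrow(tb)), tb$gene)
  k <- 0L
  for (i in seq_len(nrow(m))) {
    k <- k + 1L
    codes_a[m[i, 1]] <- k
    codes_b[m[i, 2]] <- k
  }
  del_codes <- integer(0)
  for (g in ta$gene[is.na(codes_a[ta$gene])]) {
    k <- k + 1L
    codes_a[g] <- k
    del_codes <- c(del_codes, k)
  }
  ins_codes <- integer(0)
  for (g in tb$gene[is.na(codes_b[tb$gene])]) {
    k <- k + 1L
    codes_b[g] <- k
    ins_codes <- c(ins_codes, k)
  }
  encode <- function(genome, codes) {
    lapply(genome$segments, function(s)
      list(genes = unname(codes[s$genes]) * s$orient, circ = FALSE))
  }
  start <- unname(encode(A, codes_a))
  target <- state_key(unname(encode(B, codes_b)))
  if (state_key(start) == target) return(0L)
  visited <- new.env(hash = TRUE)
  assign(state_key(start), TRUE, envir = visited)
  frontier <- list(start)
  n_states <- 1L
  for (depth in seq_len(max_depth)) {
    nxt <- list()
    for (st in frontier) {
      present <- abs(unlist(lapply(st, `[[`, "genes")))
      remaining <- setdiff(ins_codes, present)
      succ <- c(dcj_successors(st), indel_successors(st, del_codes,
                                                     remaining))
      for (s2 in succ) {
        key <- state_key(s2)
        if (key == target) return(depth)
        if (!exists(key, envir = visited)) {
          assign(key, TRUE, envir = visited)
          nxt[[length(nxt) + 1L]] <- s2
          n_states <- n_states + 1L
          if (n_states > max_states)
            stop("BFS oracle exceeded max_states (", max_states, ")")
        }
      }
    }
    if (!length(nxt)) break
    frontier <- nxt
  }
  stop("BFS oracle exceeded max_depth (", max_depth, ")")
}
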