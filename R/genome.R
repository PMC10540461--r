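#' Construct a genome of linear segments
#'
#' A genome is a set of linear segments (chromosomes, scaffolds or contigs),
#' each an ordered list of oriented genes.  Gene identifiers must be unique
#' within the genome; a segment can be read in either direction, so two
#' segments that are full reversals of each other (with all orientations
#' flipped) are considered equal.
#'
#' @param genome_id Character scalar naming the genome.
#' @param segments Named list; each element is a list with components
#'   `genes` (character vector of gene ids) and `orient` (integer vector of
#'   `+1`/`-1`, same length).  Unnamed segments are named `seg1`, `seg2`, ...
#' @return An object of class `ffdcj_genome`.
#' @examples
#' g <- genome("A", list(chr1 = list(genes = c("1", "2"), orient = c(1L, -1L))))
#' kappa(g)
#' @export
genome <- function(genome_id, segments) {
  stopifnot(is.character(genome_id), length(genome_id) == 1L, is.list(segments))
  if (length(segments) == 0L) stop("a genome needs at least one linear segment")
  if (is.null(names(segments)) || any(names(segments) == "")) {
    nm <- names(segments)
    if (is.null(nm)) nm <- rep("", length(segments))
    nm[nm == ""] <- paste0("seg", seq_along(segments))[nm == ""]
    names(segments) <- nm
  }
  if (anyDuplicated(names(segments)))
    stop("duplicate segment ids in genome '", genome_id, "'")
  segments <- lapply(segments, function(s) {
    genes <- as.character(s$genes)
    orient <- as.integer(s$orient)
    if (length(genes) == 0L) stop("empty segment in genome '", genome_id, "'")
    if (length(orient) != length(genes) || !all(orient %in% c(-1L, 1L)))
      stop("segment orientations must be +1/-1 and match the gene count")
    list(genes = genes, orient = orient)
  })
  all_genes <- unlist(lapply(segments, `[[`, "genes"), use.names = FALSE)
  dup <- all_genes[duplicated(all_genes)]
  if (length(dup))
    stop("duplicate gene id(s) in genome '", genome_id, "': ",
         paste(unique(dup), collapse = ", "))
  structure(list(genome_id = genome_id, segments = segments),
            class = "ffdcj_genome")
}

#' Number of linear segments of a genome
#' @param g An `ffdcj_genome`.
#' @return Integer segment count.
#' @export
kappa <- function(g) {
  stopifnot(inherits(g, "ffdcj_genome"))
  length(g$segments)
}

#' Number of genes of a genome
#' @param g An `ffdcj_genome`.
#' @return Integer gene count.
#' @export
n_genes <- function(g) {
  stopifnot(inherits(g, "ffdcj_genome"))
  sum(vapply(g$segments, function(s) length(s$genes), integer(1)))
}

#' Flat gene table of a genome
#'
#' @param g An `ffdcj_genome`.
#' @return A data.frame with one row per gene: `gene`, `segment`,
#'   `index` (0-based position within segment) and `orient` (+1/-1), in
#'   segment order.
#' @export
gene_table <- function(g) {
  stopifnot(inherits(g, "ffdcj_genome"))
  rows <- lapply(names(g$segments), function(sid) {
    s <- g$segments[[sid]]
    data.frame(gene = s$genes, segment = sid,
               index = seq_along(s$genes) - 1L, orient = s$orient,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' @export
print.ffdcj_genome <- function(x, ...) {
  cat("Genome '", x$genome_id, "': ", n_genes(x), " genes in ",
      kappa(x), " linear segment(s)\n", sep = "")
  for (sid in names(x$segments)) {
    s <- x$segments[[sid]]
    tok <- ifelse(s$orient < 0L, paste0("-", s$genes), s$genes)
    cat("  ", sid, ": [ ", paste(tok, collapse = " "), " ]\n", sep = "")
  }
  invisible(x)
}

# Canonical form of a segment: the lexicographically smaller of the two
# reading directions (reversal flips order and orientation).
segment_canonical <- function(s) {
  fwd <- paste(ifelse(s$orient < 0L, paste0("-", s$genes), s$genes),
               collapse = " ")
  rev_genes <- rev(s$genes)
  rev_orient <- -rev(s$orient)
  bwd <- paste(ifelse(rev_orient < 0L, paste0("-", rev_genes), rev_genes),
               collapse = " ")
  if (fwd <= bwd) fwd else bwd
}

#' Test whether two genomes are equal up to segment reversal and order
#'
#' Reading direction of a whole linear segment is meaningless, so each
#' segment is compared in canonical (direction-independent) form, and the
#' set of segments is compared regardless of order or segment ids.
#'
#' @param a,b `ffdcj_genome` objects.
#' @return Logical scalar.
#' @export
genomes_equivalent <- function(a, b) {
  ca <- sort(vapply(a$segments, segment_canonical, character(1)))
  cb <- sort(vapply(b$segments, segment_canonical, character(1)))
  length(ca) == length(cb) && all(ca == cb)
}

parse_gene_tokens <- function(tokens, line_no) {
  orient <- ifelse(startsWith(tokens, "-"), -1L, 1L)
  genes <- sub("^-", "", tokens)
  bad <- genes == "" | grepl("\\s", genes)
  if (any(bad))
    stop("malformed gene token on line ", line_no, ": '",
         tokens[which(bad)[1]], "'")
  list(genes = genes, orient = orient)
}

#' Read gene orders from a text file
#'
#' The format is one linear segment per line: a segment id followed by
#' whitespace and the space-separated oriented gene ids of the segment, where
#' a leading `-` marks reverse orientation.  A trailing `:` on the segment id
#' is tolerated.  Lines starting with `#` are comments.  An optional first
#' line of the form `>genome_id` names the genome; otherwise the file name
#' (without extension) is used.  Only linear segments are supported.
#'
#' @param path Path to the gene-order file.
#' @param genome_id Optional genome id overriding header/file name.
#' @return An `ffdcj_genome`.
#' @export
parse_gene_orders <- function(path, genome_id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  if (length(idx) && grepl("^>", lines[idx[1]])) {
    if (is.null(genome_id))
      genome_id <- sub("^>\\s*", "", lines[idx[1]])
    idx <- idx[-1]
  }
  if (is.null(genome_id))
    genome_id <- sub("\\.[^.]*$", "", basename(path))
  if (!length(idx)) stop("no segments in ", path)
  segments <- list()
  for (i in idx) {
    tokens <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    sid <- sub(":$", "", tokens[1])
    if (length(tokens) < 2L)
      stop("empty segment line ", i, " in ", path)
    if (sid %in% names(segments))
      stop("duplicate segment id '", sid, "' on line ", i)
    segments[[sid]] <- parse_gene_tokens(tokens[-1], i)
  }
  genome(genome_id, segments)
}

#' Write gene orders to a text file
#'
#' Inverse of [parse_gene_orders()]; round-trips up to whitespace.
#'
#' @param g An `ffdcj_genome`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_orders <- function(g, path) {
  stopifnot(inherits(g, "ffdcj_genome"))
  lines <- c(paste0(">", g$genome_id),
             vapply(names(g$segments), function(sid) {
               s <- g$segments[[sid]]
               tok <- ifelse(s$orient < 0L, paste0("-", s$genes), s$genes)
               paste0(sid, "\t", paste(tok, collapse = " "))
             }, character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' Parse a genome from bracket notation
#'
#' Convenience constructor for examples and tests: segments are given in
#' square brackets, genes space-separated, `-` marking reverse orientation,
#' e.g. `"[1 2 3 4][5 -6]"`.
#'
#' @param genome_id Genome id.
#' @param text Bracket-notation string.
#' @return An `ffdcj_genome`.
#' @examples
#' genome_from_string("A", "[1 2 3 4][5 -6]")
#' @export
genome_from_string <- function(genome_id, text) {
  m <- regmatches(text, gregexpr("\\[[^][]*\\]", text))[[1]]
  if (!length(m)) stop("no [ ... ] segments found")
  segs <- lapply(m, function(x) {
    tokens <- strsplit(trimws(gsub("[][]", "", x)), "\\s+")[[1]]
    parse_gene_tokens(tokens, NA)
  })
  names(segs) <- paste0("seg", seq_along(segs))
  genome(genome_id, segs)
}

#' Read tabular similarity hits (BLAST/DIAMOND outfmt-6 dialect)
#'
#' Expects tab-separated rows with the query id in column 1, the subject id
#' in column 2 and the bitscore in the last column; intermediate columns are
#' ignored.  Duplicate (query, subject) pairs (multiple HSPs) collapse to
#' their maximum bitscore.
#'
#' @param path Path to the tabular hits file.
#' @return A `ffdcj_hits` data.frame with columns `query`, `subject`,
#'   `bitscore`.
#' @export
parse_tabular_hits <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (!length(lines))
    return(hits_table(character(0), character(0), numeric(0)))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- lengths(parts)
  if (any(ncols < 3L))
    stop("tabular hits need at least 3 tab-separated columns (line ",
         which(ncols < 3L)[1], ")")
  query <- vapply(parts, `[[`, character(1), 1L)
  subject <- vapply(parts, `[[`, character(1), 2L)
  raw <- vapply(parts, function(p) p[[length(p)]], character(1))
  bitscore <- suppressWarnings(as.numeric(raw))
  if (anyNA(bitscore))
    stop("non-numeric bitscore on line ", which(is.na(bitscore))[1])
  hits_table(query, subject, bitscore)
}

#' Construct a bitscore table
#'
#' @param query,subject Character vectors of gene ids.
#' @param bitscore Positive numeric vector.
#' @return A `ffdcj_hits` data.frame; duplicates keep the maximum bitscore.
#' @export
hits_table <- function(query, subject, bitscore) {
  stopifnot(length(query) == length(subject),
            length(query) == length(bitscore))
  bitscore <- as.numeric(bitscore)
  if (any(!is.finite(bitscore) | bitscore <= 0))
    stop("bitscores must be positive and finite")
  df <- data.frame(query = as.character(query),
                   subject = as.character(subject),
                   bitscore = bitscore, stringsAsFactors = FALSE)
  if (nrow(df)) {
    key <- paste(df$query, df$subject, sep = "\r")
    mx <- tapply(df$bitscore, key, max)
    first <- !duplicated(key)
    df <- df[first, , drop = FALSE]
    df$bitscore <- as.numeric(mx[paste(df$query, df$subject, sep = "\r")])
    rownames(df) <- NULL
  }
  class(df) <- c("ffdcj_hits", "data.frame")
  df
}

#' Construct a family set
#'
#' @param families List of character vectors of gene ids; families must be
#'   pairwise disjoint.
#' @param provenance Character label recording where the families came from.
#' @return An object of class `ffdcj_family_set`.
#' @export
family_set <- function(families, provenance = "unspecified") {
  stopifnot(is.list(families))
  families <- lapply(families, function(f) sort(unique(as.character(f))))
  all_genes <- unlist(families, use.names = FALSE)
  dup <- all_genes[duplicated(all_genes)]
  if (length(dup))
    stop("gene(s) in more than one family: ",
         paste(unique(dup), collapse = ", "))
  structure(list(families = families, provenance = provenance),
            class = "ffdcj_family_set")
}

#' @export
print.ffdcj_family_set <- function(x, ...) {
  sizes <- lengths(x$families)
  cat("Family set (", x$provenance, "): ", length(x$families),
      " families, ", sum(sizes), " genes\n", sep = "")
  if (length(sizes))
    cat("  sizes: ", paste(utils::head(sort(unique(sizes)), 10),
                           collapse = " "), "\n", sep = "")
  invisible(x)
}

#' Read a family list file
#'
#' One family per line, whitespace-separated gene ids.
#'
#' @param path Path to the file.
#' @param provenance Label stored on the result (default: file name).
#' @return An `ffdcj_family_set`.
#' @export
read_families <- function(path, provenance = basename(path)) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  fams <- lapply(lines, function(l) strsplit(trimws(l), "\\s+")[[1]])
  family_set(fams, provenance = provenance)
}

#' Write a family list file
#'
#' @param fs An `ffdcj_family_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_families <- function(fs, path) {
  stopifnot(inherits(fs, "ffdcj_family_set"))
  writeLines(vapply(fs$families, paste, character(1), collapse = " "), path)
  invisible(path)
}
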