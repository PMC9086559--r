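#' Parse a circBase-style circRNA id
#'
#' Ids of the form `chrN:start-end` with 1-based, fully-closed genomic
#' coordinates (e.g. `chr8:71244603-71271897`).
#'
#' @param id character vector of circRNA ids.
#' @return data.frame with `chrom`, `start`, `end`.
#' @export
parse_circ_id <- function(id) {
  m <- regmatches(id, regexec("^(chr[0-9XYM]+):([0-9]+)-([0-9]+)$", id))
  bad <- vapply(m, length, 1L) != 4L
  if (any(bad)) stop("malformed circRNA id: ", id[bad][1])
  data.frame(chrom = vapply(m, `[`, "", 2),
             start = as.integer(vapply(m, `[`, "", 3)),
             end = as.integer(vapply(m, `[`, "", 4)),
             stringsAsFactors = FALSE)
}

#' Read a count matrix from TSV
#'
#' Tab-separated, header row of sample ids, feature ids in column 1.
#' Counts must be non-negative integers and feature ids unique.
#'
#' @param path file path.
#' @param lib_sizes optional per-sample library sizes.
#' @param kind matrix kind, default `"count"`.
#' @return an `ExprMatrix`.
#' @export
read_counts <- function(path, lib_sizes = NULL, kind = "count") {
  d <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(d[[1]])
  if (anyDuplicated(ids))
    stop("duplicate feature ids in ", path, ": ",
         ids[duplicated(ids)][1])
  v <- as.matrix(d[, -1, drop = FALSE])
  if (kind == "count") {
    if (any(v != round(v)))
      stop("non-integer counts in ", path)
    storage.mode(v) <- "integer"
  }
  rownames(v) <- ids
  expr_matrix(v, kind, lib_sizes = lib_sizes)
}

#' Write a matrix or data.frame as TSV
#'
#' For an `ExprMatrix`, feature ids go in a first column named `feature_id`.
#'
#' @param x `ExprMatrix`, matrix or data.frame.
#' @param path output path.
#' @export
write_table <- function(x, path) {
  if (inherits(x, "ExprMatrix")) x <- x$values
  if (is.matrix(x)) {
    x <- data.frame(feature_id = rownames(x), x, check.names = FALSE,
                    stringsAsFactors = FALSE)
  }
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read sequences from FASTA
#'
#' Accepts DNA or RNA alphabets and normalises to RNA (U) internally.
#'
#' @param path FASTA file.
#' @return named character vector of RNA sequences.
#' @export
read_fasta <- function(path) {
  s <- Biostrings::readBStringSet(path)
  v <- stats::setNames(as.character(s), names(s))
  vapply(v, normalize_rna, "")
}

#' Write sequences to FASTA
#' @param seqs named character vector.
#' @param path output path.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(
    Biostrings::BStringSet(unlist(seqs)), path)
  invisible(path)
}

#' Read an undirected edge list from TSV or SIF
#'
#' TSV: two columns (`from`, `to`), header optional. SIF: whitespace
#' separated `source interaction target [target2 ...]` lines; the
#' interaction type is returned in a third column.
#'
#' @param path input file.
#' @param format `"tsv"` or `"sif"`; guessed from the extension by default.
#' @return data.frame with `from`, `to` and, for SIF, `type`.
#' @export
read_edges <- function(path, format = NULL) {
  if (is.null(format))
    format <- if (grepl("\\.sif$", path, ignore.case = TRUE)) "sif" else "tsv"
  if (format == "sif") {
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    out <- do.call(rbind, lapply(lines, function(l) {
      f <- strsplit(trimws(l), "[ \t]+")[[1]]
      if (length(f) < 3) stop("malformed SIF line: ", l)
      data.frame(from = f[1], to = f[3:length(f)], type = f[2],
                 stringsAsFactors = FALSE)
    }))
    rownames(out) <- NULL
    return(out)
  }
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("from", "to") %in% names(d))) {
    d <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
    names(d)[1:2] <- c("from", "to")
  }
  d[, intersect(c("from", "to", "type"), names(d)), drop = FALSE]
}

#' Export a typed network to SIF and/or GraphML
#'
#' SIF lines are `source type target`; GraphML carries a node attribute
#' `kind` and an edge attribute `energy` where available.
#'
#' @param edges data.frame with `from`, `to` and optional `type`,
#'   `energy` columns.
#' @param path output path; format decided by `format`.
#' @param format `"sif"` or `"graphml"`.
#' @param node_kinds optional named character vector node -> kind.
#' @export
write_network <- function(edges, path, format = c("sif", "graphml"),
                          node_kinds = NULL) {
  format <- match.arg(format)
  if (nrow(edges) == 0 && format == "sif") {
    writeLines(character(0), path)
    return(invisible(path))
  }
  type <- if ("type" %in% names(edges)) edges$type else rep("pp", nrow(edges))
  if (format == "sif") {
    writeLines(paste(edges$from, type, edges$to), path)
    return(invisible(path))
  }
  g <- igraph::graph_from_data_frame(
    data.frame(from = edges$from, to = edges$to, stringsAsFactors = FALSE),
    directed = FALSE)
  igraph::E(g)$type <- type
  if ("energy" %in% names(edges)) igraph::E(g)$energy <- edges$energy
  if (!is.null(node_kinds))
    igraph::V(g)$kind <- unname(node_kinds[igraph::V(g)$name])
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
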