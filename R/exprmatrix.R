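#' Expression matrix container
#'
#' A light S3 container for a feature-by-sample abundance matrix together
#' with the metadata the quantification formulas need: per-sample library
#' sizes (total mapped reads; total mapped fragments for mRNA, total mapped
#' reads for back-splice junction tables) and per-feature exon lengths in
#' kilobases (required for FPKM only).
#'
#' @param values numeric matrix, features in rows, samples in columns;
#'   must carry unique rownames (feature ids) and colnames (sample ids).
#' @param kind one of `"count"`, `"FPKM"`, `"SRPBM"`.
#' @param lib_sizes numeric vector of total mapped reads per sample, or
#'   `NULL` for normalised kinds.
#' @param feature_lengths numeric vector of exon lengths in kb, or `NULL`.
#' @return an object of class `ExprMatrix`.
#' @export
expr_matrix <- function(values, kind = c("count", "FPKM", "SRPBM"),
                        lib_sizes = NULL, feature_lengths = NULL) {
  kind <- match.arg(kind)
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("'values' must have feature rownames and sample colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate feature ids: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample ids: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]), collapse = ", "))
  if (any(values < 0)) stop("expression values must be non-negative")
  if (!is.null(lib_sizes)) {
    if (length(lib_sizes) != ncol(values))
      stop("lib_sizes length must equal the number of samples")
    if (any(lib_sizes <= 0)) stop("library sizes must be positive")
    names(lib_sizes) <- colnames(values)
  }
  if (!is.null(feature_lengths)) {
    if (length(feature_lengths) != nrow(values))
      stop("feature_lengths length must equal the number of features")
    names(feature_lengths) <- rownames(values)
  }
  structure(list(values = values, kind = kind, lib_sizes = lib_sizes,
                 feature_lengths = feature_lengths),
            class = "ExprMatrix")
}

#' @method print ExprMatrix
#' @export
print.ExprMatrix <- function(x, ...) {
  cat(sprintf("ExprMatrix [%s]: %d features x %d samples\n",
              x$kind, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' @export
dim.ExprMatrix <- function(x) dim(x$values)

feature_ids <- function(x) rownames(x$values)
sample_ids  <- function(x) colnames(x$values)

stopifnot_counts <- function(x) {
  if (!inherits(x, "ExprMatrix")) stop("expected an ExprMatrix")
  if (x$kind != "count") stop("expected a count ExprMatrix, got ", x$kind)
}

#' FPKM quantification
#'
#' Fragments per kilobase of exon per million mapped reads:
#' \deqn{FPKM_{ij} = \frac{c_{ij}}{(N_j/10^6)\, L_i}}
#' where \eqn{c_{ij}} is the fragment count, \eqn{N_j} the sample's total
#' mapped reads and \eqn{L_i} the exon length in kb.
#'
#' @param counts a count `ExprMatrix` with `lib_sizes` and
#'   `feature_lengths` set.
#' @return an `ExprMatrix` of kind `"FPKM"`.
#' @export
fpkm <- function(counts) {
  stopifnot_counts(counts)
  if (is.null(counts$lib_sizes)) stop("lib_sizes required for FPKM")
  if (is.null(counts$feature_lengths)) stop("feature_lengths (kb) required for FPKM")
  if (any(counts$feature_lengths <= 0)) stop("feature lengths must be positive")
  v <- counts$values /
    outer(counts$feature_lengths, counts$lib_sizes / 1e6)
  expr_matrix(v, "FPKM", feature_lengths = counts$feature_lengths)
}

#' SRPBM quantification for back-splice junction reads
#'
#' Spliced reads per billion mapped reads:
#' \deqn{SRPBM_{ij} = \frac{c_{ij}}{N_j/10^9}}
#' with \eqn{c_{ij}} the number of reads spanning the back-splice junction
#' and \eqn{N_j} the total mapped reads. No length term: every junction
#' read covers the same single junction.
#'
#' @param junction_counts a count `ExprMatrix` with `lib_sizes` set.
#' @return an `ExprMatrix` of kind `"SRPBM"`.
#' @export
srpbm <- function(junction_counts) {
  stopifnot_counts(junction_counts)
  if (is.null(junction_counts$lib_sizes)) stop("lib_sizes required for SRPBM")
  v <- sweep(junction_counts$values, 2, junction_counts$lib_sizes / 1e9, "/")
  expr_matrix(v, "SRPBM")
}
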