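#' Weighted Kolmogorov-Smirnov enrichment score
#'
#' Walks down a ranked gene list; at a gene-set member the running sum
#' rises by |metric|^weight normalised by the set's total weighted
#' metric, at a non-member it falls by 1/(N - N_set). The enrichment
#' score is the running-sum value of largest magnitude. `weight = 0`
#' reduces to the classic (unweighted) KS statistic; `weight = 1` is the
#' standard weighted form.
#'
#' @param ranking data.frame with `gene_id` and `metric`, sorted by
#'   decreasing metric (re-sorted defensively).
#' @param gene_set character vector of member ids.
#' @param weight exponent on |metric| for hits (default 1).
#' @return list with `es` and the `running` sum (one value per rank).
#' @export
enrichment_score <- function(ranking, gene_set, weight = 1) {
  if (anyDuplicated(ranking$gene_id)) stop("duplicate gene ids in ranking")
  o <- order(-ranking$metric)
  ids <- ranking$gene_id[o]; met <- ranking$metric[o]
  inset <- ids %in% gene_set
  n_hit <- sum(inset)
  if (n_hit == 0) stop("gene set does not intersect the ranking")
  if (n_hit == length(ids)) stop("gene set covers the whole ranking")
  w <- abs(met)^weight
  denom_hit <- sum(w[inset])
  if (denom_hit == 0) stop("all in-set metric weights are zero")
  step <- ifelse(inset, w / denom_hit, -1 / (length(ids) - n_hit))
  running <- cumsum(step)
  es <- running[which.max(abs(running))]
  list(es = es, running = running)
}

#' GSEA with a gene-label permutation null
#'
#' For each gene set, the null distribution of the enrichment score comes
#' from `n_perm` random same-size gene sets. NES divides the observed ES
#' by the mean |null ES| of matching sign; the p value is the add-one
#' permutation estimate against same-sign nulls. A set is flagged
#' significant when |NES| > 2 and p < 0.05.
#'
#' @param ranking data.frame with `gene_id`, `metric`.
#' @param gene_sets named list of character vectors.
#' @param n_perm number of permutations (>= 100).
#' @param weight hit-weight exponent.
#' @param seed integer RNG seed.
#' @return data.frame `set_id`, `es`, `nes`, `p`, `n_perm`, `significant`.
#' @export
gsea <- function(ranking, gene_sets, n_perm = 1000, weight = 1, seed = 1) {
  if (n_perm < 100) stop("n_perm must be >= 100")
  set.seed(seed)
  ids <- ranking$gene_id
  res <- lapply(names(gene_sets), function(sid) {
    gs <- intersect(gene_sets[[sid]], ids)
    obs <- enrichment_score(ranking, gs, weight)$es
    null <- vapply(seq_len(n_perm), function(i)
      enrichment_score(ranking, sample(ids, length(gs)), weight)$es,
      numeric(1))
    same <- null[sign(null) == sign(obs)]
    if (length(same) == 0 || mean(abs(same)) == 0) {
      if (all(null == 0)) stop("degenerate permutation null (all zero)")
      same <- null
    }
    nes <- obs / mean(abs(same))
    p <- (1 + sum(abs(same) >= abs(obs))) / (1 + length(same))
    data.frame(set_id = sid, es = obs, nes = nes, p = p,
               n_perm = n_perm, significant = abs(nes) > 2 & p < 0.05,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Read gene sets in GMT format
#'
#' One set per line: name, description, then member ids, tab-separated.
#'
#' @param path GMT file.
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  out <- lapply(lines, function(l) {
    f <- strsplit(l, "\t")[[1]]
    if (length(f) < 3) stop("malformed GMT line: ", l)
    f[-(1:2)]
  })
  names(out) <- vapply(lines, function(l) strsplit(l, "\t")[[1]][1], "")
  out
}
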