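#' Assemble the circRNA-miRNA-mRNA ceRNA network
#'
#' For each (circRNA, mRNA) pair, the shared miRNA set is the set of
#' miRNAs with at least one reported site on both molecules. A pair is
#' retained when (i) the shared set is non-empty, (ii) the two molecules
#' have concordant differential directions (ceRNA sponging implies
#' synergistic expression trends: both up or both down), and (iii) the sum
#' over shared miRNAs of the best (most negative) site energy on the
#' circRNA plus the best site energy on the mRNA is strictly below
#' `energy_sum_max`. One triple is emitted per (circ, shared miRNA, mRNA).
#'
#' @param circ_de,mrna_de filtered DE tables from [call_de()] with a
#'   `direction` column.
#' @param circ_hits,mrna_hits hit tables from [scan_targets()] against the
#'   circRNA and mRNA sequence sets.
#' @param energy_sum_max pair-level energy-sum ceiling in kcal/mol
#'   (exclusive; default -90).
#' @return list with `triples` (data.frame circ_id/mir_id/mrna_id/
#'   circ_direction/mrna_direction/sum_max_energy), `edges` (typed edge
#'   table), and `node_kinds`.
#' @export
build_cerna <- function(circ_de, mrna_de, circ_hits, mrna_hits,
                        energy_sum_max = -90) {
  empty <- data.frame(circ_id = character(), mir_id = character(),
                      mrna_id = character(), circ_direction = character(),
                      mrna_direction = character(),
                      sum_max_energy = numeric(), stringsAsFactors = FALSE)
  if (nrow(circ_hits) == 0 || nrow(mrna_hits) == 0)
    return(build_from_triples(empty))
  cd <- stats::setNames(circ_de$direction, circ_de$feature_id)
  md <- stats::setNames(mrna_de$direction, mrna_de$feature_id)
  circ_hits <- circ_hits[circ_hits$target_id %in% names(cd), , drop = FALSE]
  mrna_hits <- mrna_hits[mrna_hits$target_id %in% names(md), , drop = FALSE]
  # best (most negative) site energy per (miRNA, molecule)
  best <- function(h) {
    if (nrow(h) == 0) return(h)
    agg <- stats::aggregate(energy ~ mirna_id + target_id, data = h, FUN = min)
    agg
  }
  bc <- best(circ_hits); bm <- best(mrna_hits)
  triples <- empty
  for (circ in sort(unique(bc$target_id))) {
    mir_c <- bc[bc$target_id == circ, , drop = FALSE]
    for (mrna in sort(unique(bm$target_id))) {
      if (cd[[circ]] != md[[mrna]]) next
      mir_m <- bm[bm$target_id == mrna, , drop = FALSE]
      shared <- sort(intersect(mir_c$mirna_id, mir_m$mirna_id))
      if (length(shared) == 0) next
      esum <- sum(mir_c$energy[match(shared, mir_c$mirna_id)] +
                  mir_m$energy[match(shared, mir_m$mirna_id)])
      if (esum >= energy_sum_max) next
      triples <- rbind(triples, data.frame(
        circ_id = circ, mir_id = shared, mrna_id = mrna,
        circ_direction = cd[[circ]], mrna_direction = md[[mrna]],
        sum_max_energy = esum, stringsAsFactors = FALSE))
    }
  }
  triples <- triples[order(triples$circ_id, triples$mir_id,
                           triples$mrna_id), , drop = FALSE]
  build_from_triples(triples)
}

#' Maximal clique centrality scores
#'
#' MCC(v) is the sum of (|C| - 1)! over every maximal clique C containing
#' v; an isolated node sits in the singleton maximal clique and scores
#' (1-1)! = 1. Maximal cliques are enumerated with Bron-Kerbosch (with
#' pivoting, via igraph); ranking is by decreasing score with lexicographic
#' tie-break on the node id.
#'
#' @param edges data.frame with `from`/`to`, or an igraph graph. Parallel
#'   edges and self-loops are dropped.
#' @param nodes optional full node set (to include isolated nodes).
#' @param max_cliques_budget abort with an error if the graph holds more
#'   maximal cliques than this.
#' @return data.frame `gene_id`, `mcc`, `rank`, sorted by rank.
#' @export
mcc_scores <- function(edges, nodes = NULL, max_cliques_budget = 1e5) {
  g <- if (inherits(edges, "igraph")) edges else {
    if (nrow(edges) == 0) {
      igraph::make_empty_graph(directed = FALSE) |>
        igraph::add_vertices(length(nodes), name = as.character(nodes))
    } else {
      igraph::graph_from_data_frame(edges[, c("from", "to")],
                                    directed = FALSE,
                                    vertices = if (is.null(nodes)) NULL
                                               else unique(as.character(nodes)))
    }
  }
  g <- igraph::simplify(g)
  if (igraph::vcount(g) == 0) {
    warning("empty graph")
    return(data.frame(gene_id = character(), mcc = numeric(),
                      rank = integer(), stringsAsFactors = FALSE))
  }
  n_cl <- igraph::count_max_cliques(g)
  if (n_cl > max_cliques_budget)
    stop(sprintf("clique enumeration budget exceeded (%d > %g maximal cliques)",
                 n_cl, max_cliques_budget))
  cl <- igraph::max_cliques(g)
  mcc <- stats::setNames(rep(0, igraph::vcount(g)), igraph::V(g)$name)
  for (C in cl) {
    w <- factorial(length(C) - 1)
    ids <- igraph::V(g)$name[as.integer(C)]
    mcc[ids] <- mcc[ids] + w
  }
  out <- data.frame(gene_id = names(mcc), mcc = unname(mcc),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$mcc, out$gene_id), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Top hub genes by MCC
#'
#' @param scores output of [mcc_scores()].
#' @param k number of hubs (default 10).
#' @return character vector of the first `k` gene ids by rank.
#' @export
top_hubs <- function(scores, k = 10) {
  if (k < 1) stop("k must be >= 1")
  if (nrow(scores) == 0) {
    warning("no nodes to rank")
    return(character(0))
  }
  if (k > nrow(scores)) {
    warning("k exceeds node count; returning all nodes")
    k <- nrow(scores)
  }
  scores$gene_id[seq_len(k)]
}

#' Restrict a ceRNA network to a set of mRNAs
#'
#' Keeps triples whose mRNA is in `keep_mrnas` and drops orphaned miRNA
#' and circRNA nodes.
#'
#' @param net list from [build_cerna()].
#' @param keep_mrnas character vector of mRNA ids (must be mRNA nodes of
#'   the network; empty vector allowed).
#' @return a ceRNA network list of the same shape.
#' @export
subnetwork <- function(net, keep_mrnas) {
  mrnas <- unique(net$triples$mrna_id)
  unknown <- setdiff(keep_mrnas, mrnas)
  if (length(unknown) > 0)
    stop("unknown mRNA id(s): ", paste(unknown, collapse = ", "))
  build_from_triples(net$triples[net$triples$mrna_id %in% keep_mrnas, ,
                                 drop = FALSE])
}

build_from_triples <- function(tr) {
  rownames(tr) <- NULL
  if (nrow(tr) == 0)
    return(list(triples = tr,
                edges = data.frame(from = character(), to = character(),
                                   type = character(), stringsAsFactors = FALSE),
                node_kinds = character(0)))
  e1 <- unique(data.frame(from = tr$circ_id, to = tr$mir_id,
                          type = "circ-mir", stringsAsFactors = FALSE))
  e2 <- unique(data.frame(from = tr$mir_id, to = tr$mrna_id,
                          type = "mir-mrna", stringsAsFactors = FALSE))
  kinds <- c(stats::setNames(rep("circRNA", length(unique(tr$circ_id))),
                             unique(tr$circ_id)),
             stats::setNames(rep("miRNA", length(unique(tr$mir_id))),
                             unique(tr$mir_id)),
             stats::setNames(rep("mRNA", length(unique(tr$mrna_id))),
                             unique(tr$mrna_id)))
  list(triples = tr, edges = rbind(e1, e2), node_kinds = kinds)
}
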