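#' Compose a coherent synthetic ceRNA study
#'
#' Builds, from one synthesis block and one seed, all inputs of the full
#' chain with a consistent planted truth:
#' \itemize{
#'   \item paired tumor/normal mRNA and circRNA count matrices with
#'     planted fold-changes;
#'   \item RNA sequence sets where each planted (circRNA, mRNA) ceRNA
#'     pair shares `mirs_per_pair` miRNAs whose exact complements are
#'     embedded in both molecules — sequences are named by the count
#'     matrix feature ids so downstream joins are direct;
#'   \item a PPI edge list over candidate genes with a planted clique
#'     containing the prognostic signature genes;
#'   \item a survival cohort whose hazard is driven by the signature
#'     genes.
#' }
#' Planted circRNAs and mRNAs are drawn from the count-matrix planted DE
#' features so that expression directions are concordant within a pair
#' (half up/up, half down/down).
#'
#' @param sy synthesis block of [cerna_config()].
#' @param seed integer seed.
#' @return list with `mrna`, `circ` (counts + truth), `seqs`, `ppi`,
#'   `ppi_nodes`, `survival`, and a merged `truth` holding
#'   `planted_triples`, `planted_cliques`, `prognostic_betas`.
#' @export
gen_cerna_scenario <- function(sy, seed = 1) {
  mrna <- gen_count_matrix(sy$n_mrna_features, sy$n_pairs, sy$frac_de,
                           sy$fc_de, sy$dispersion, sy$mrna_lib,
                           feature_prefix = "gene",
                           seed = derive_seed(seed, 1L))
  circ <- gen_count_matrix(sy$n_circ_features, sy$n_pairs, sy$frac_de,
                           sy$fc_de, sy$dispersion, sy$circ_lib,
                           circ_ids = TRUE, seed = derive_seed(seed, 2L))
  npp <- sy$n_planted_pairs
  pick_pair_features <- function(truth, n) {
    up <- truth$de_features$feature_id[truth$de_features$direction == "up"]
    dn <- truth$de_features$feature_id[truth$de_features$direction == "down"]
    n_up <- ceiling(n / 2)
    if (length(up) < n_up || length(dn) < n - n_up)
      stop("not enough planted DE features for the requested ceRNA pairs")
    c(up[seq_len(n_up)], dn[seq_len(n - n_up)])
  }
  circ_feats <- pick_pair_features(circ$truth, npp)
  mrna_feats <- pick_pair_features(mrna$truth, npp)
  dir_of <- function(truth, ids)
    truth$de_features$direction[match(ids, truth$de_features$feature_id)]

  n_mir <- npp * sy$mirs_per_pair + sy$n_decoy_mirna
  plan <- do.call(rbind, lapply(seq_len(npp), function(k) {
    mirs <- sprintf("mir-%03d", (k - 1) * sy$mirs_per_pair +
                      seq_len(sy$mirs_per_pair))
    rbind(data.frame(mir = mirs, target = sprintf("circ-%03d", k),
                     n_sites = 1, stringsAsFactors = FALSE),
          data.frame(mir = mirs, target = sprintf("mrna-%03d", k),
                     n_sites = 1, stringsAsFactors = FALSE))
  }))
  seqs <- gen_sequences(n_mir, npp + sy$n_decoy_circ, npp + sy$n_decoy_mrna,
                        site_plan = plan, seed = derive_seed(seed, 3L))
  # rename sequences to feature ids: planted ones onto planted DE features,
  # decoys onto non-DE features
  decoy_feats <- function(truth, counts, n, exclude) {
    pool <- setdiff(feature_ids(counts),
                    c(truth$de_features$feature_id, exclude))
    pool[seq_len(n)]
  }
  circ_names <- c(circ_feats, decoy_feats(circ$truth, circ$counts,
                                          sy$n_decoy_circ, circ_feats))
  mrna_names <- c(mrna_feats, decoy_feats(mrna$truth, mrna$counts,
                                          sy$n_decoy_mrna, mrna_feats))
  names(seqs$circs) <- circ_names
  names(seqs$mrnas) <- mrna_names
  seqs$truth$planted_sites$target_id <- c(circ_names, mrna_names)[
    match(seqs$truth$planted_sites$target_id,
          c(sprintf("circ-%03d", seq_along(circ_names)),
            sprintf("mrna-%03d", seq_along(mrna_names))))]

  triples <- do.call(rbind, lapply(seq_len(npp), function(k) {
    mirs <- sprintf("mir-%03d", (k - 1) * sy$mirs_per_pair +
                      seq_len(sy$mirs_per_pair))
    data.frame(circ_id = circ_feats[k], mir_id = mirs,
               mrna_id = mrna_feats[k], stringsAsFactors = FALSE)
  }))

  ## PPI over the network mRNAs plus extra DE genes
  sig_genes <- mrna_feats[seq_len(min(sy$n_signature, npp))]
  other_de <- setdiff(mrna$truth$de_features$feature_id, mrna_feats)
  extra <- other_de[seq_len(min(sy$ppi_extra_nodes, length(other_de)))]
  ppi_nodes <- unique(c(mrna_feats, extra))
  clique <- unique(c(sig_genes,
                     setdiff(ppi_nodes, sig_genes)[
                       seq_len(max(0, sy$clique_size - length(sig_genes)))]))
  ppi <- gen_ppi(ppi_nodes, planted_cliques = list(clique),
                 noise_edges = sy$ppi_noise_edges,
                 seed = derive_seed(seed, 4L))

  ## survival cohort over all PPI genes; hazard driven by the signature
  betas <- stats::setNames(rep(sy$beta, length(sig_genes)), sig_genes)
  if (isTRUE(sy$no_survival)) {
    surv <- NULL
    betas <- numeric(0)
  } else {
    surv <- gen_survival(sy$n_patients, betas = betas,
                         n_null_genes = 0, censor_rate = sy$censor_rate,
                         seed = derive_seed(seed, 6L))
    # add null expression for the remaining PPI genes
    nulls <- setdiff(ppi_nodes, sig_genes)
    if (length(nulls) > 0) {
      set.seed(derive_seed(seed, 8L))
      xn <- matrix(stats::rnorm(sy$n_patients * length(nulls)),
                   sy$n_patients, dimnames = list(NULL, nulls))
      surv$survival <- cbind(surv$survival, as.data.frame(xn))
    }
  }

  truth <- synthetic_truth(
    de_features = rbind(mrna$truth$de_features, circ$truth$de_features),
    planted_sites = seqs$truth$planted_sites,
    planted_triples = triples,
    planted_cliques = list(clique),
    prognostic_betas = betas,
    seed = seed)
  list(mrna = mrna, circ = circ, seqs = seqs, ppi = ppi,
       ppi_nodes = ppi_nodes, survival = surv,
       pair_directions = data.frame(circ_id = circ_feats,
                                    mrna_id = mrna_feats,
                                    circ_dir = dir_of(circ$truth, circ_feats),
                                    mrna_dir = dir_of(mrna$truth, mrna_feats),
                                    stringsAsFactors = FALSE),
       truth = truth)
}
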