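#' Default pipeline configuration
#'
#' Thresholds follow the published screening standards: mRNA DE at
#' |logFC| > 2 with BH-adjusted p < 0.05, circRNA DE at |logFC| > 2 with
#' raw p < 0.05, miRNA sites at alignment score > 140 and duplex energy
#' < -20 kcal/mol, ceRNA pairs at energy sum < -90 kcal/mol, top-10 MCC
#' hubs, and ROC horizons at 3/5/7 years. The synthesis block defines the
#' simulated study: 8 tumor/normal pairs, negative-binomial counts, a
#' sequence set with sites planted for the true triples, a PPI graph with
#' the signature genes inside a planted clique, and a 136-patient
#' survival cohort driven by three prognostic genes.
#'
#' @param seed global integer seed; stage seeds are derived from it.
#' @param ... overrides for any top-level config entry.
#' @return nested configuration list.
#' @export
cerna_config <- function(seed = 1, ...) {
  cfg <- list(
    seed = seed,
    thresholds = list(min_abs_logfc = 2, alpha = 0.05,
                      min_score = 140, max_energy = -20,
                      energy_sum_max = -90, k_hubs = 10,
                      horizons = c(3, 5, 7)),
    synthesis = list(
      n_mrna_features = 2000, n_circ_features = 300, n_pairs = 8,
      frac_de = 0.05, fc_de = 6, dispersion = 0.1,
      mrna_lib = 2e7, circ_lib = 5e7,
      n_planted_pairs = 4,          # planted (circ, mRNA) ceRNA pairs
      mirs_per_pair = 2,            # shared miRNAs per planted pair
      n_decoy_mirna = 2, n_decoy_circ = 2, n_decoy_mrna = 4,
      clique_size = 6, ppi_extra_nodes = 30, ppi_noise_edges = 40,
      n_patients = 136, censor_rate = 0.3, beta = 1,
      n_signature = 3),
    lasso = list(n_folds = 5, rule = "min"),
    gsea = list(n_perm = 1000, weight = 1))
  dots <- list(...)
  cfg[names(dots)] <- dots
  cfg
}

derive_seed <- function(seed, k) (seed * 97L + k * 1009L) %% 2147483629L

#' Run the full ceRNA inference chain on a synthetic study
#'
#' Synthesises the study described by `config$synthesis` (paired count
#' matrices, sequence sets with planted binding sites, a PPI graph, a
#' survival cohort), then runs differential expression, miRNA target
#' scanning, ceRNA network assembly, GSEA of the network mRNAs, MCC hub
#' ranking, univariate-Cox screening plus LASSO-Cox signature fitting,
#' risk stratification with time-dependent ROC, and the signature
#' subnetwork. All tables, networks, the model JSON, a truth-vs-output
#' report and a manifest are written under `out_dir`.
#'
#' @param config list from [cerna_config()] (or a YAML file path readable
#'   by [read_config()]).
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list with every stage result (see the written
#'   `report.json` for the planted-truth comparison).
#' @export
run_all <- function(config = cerna_config(), out_dir = tempfile("cerna_run_")) {
  if (is.character(config)) config <- read_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  th <- config$thresholds; sy <- config$synthesis
  seed <- config$seed
  msg <- function(...) message("[cernaforge] ", sprintf(...))

  ## --- stage 1: synthesis -------------------------------------------------
  msg("synthesising study (seed %d)", seed)
  scen <- gen_cerna_scenario(sy, seed)
  write_table(scen$mrna$counts, file.path(out_dir, "counts_mrna.tsv"))
  write_table(scen$circ$counts, file.path(out_dir, "counts_circ.tsv"))
  write_fasta(c(scen$seqs$mirnas, scen$seqs$circs, scen$seqs$mrnas),
              file.path(out_dir, "sequences.fa"))
  write_table(scen$ppi$edges, file.path(out_dir, "ppi_edges.tsv"))
  if (!is.null(scen$survival))
    write_table(scen$survival$survival, file.path(out_dir, "survival.tsv"))

  ## --- stage 2: differential expression ----------------------------------
  msg("differential expression")
  groups <- rep(c("normal", "tumor"), each = sy$n_pairs)
  de_m <- de_test(scen$mrna$counts, groups)
  de_c <- de_test(scen$circ$counts, groups)
  de_m_call <- call_de(de_m, th$min_abs_logfc, th$alpha, use_adjusted = TRUE)
  de_c_call <- call_de(de_c, th$min_abs_logfc, th$alpha, use_adjusted = FALSE)
  write_table(de_m, file.path(out_dir, "de_mrna.tsv"))
  write_table(de_c, file.path(out_dir, "de_circ.tsv"))

  ## --- stage 3: target scanning -------------------------------------------
  msg("scanning miRNA target sites")
  hits_c <- scan_targets(scen$seqs$mirnas, scen$seqs$circs,
                         th$min_score, th$max_energy)
  hits_m <- scan_targets(scen$seqs$mirnas, scen$seqs$mrnas,
                         th$min_score, th$max_energy)
  write_table(hits_c, file.path(out_dir, "hits_circ.tsv"))
  write_table(hits_m, file.path(out_dir, "hits_mrna.tsv"))

  ## --- stage 4: ceRNA network ---------------------------------------------
  msg("assembling ceRNA network")
  net <- build_cerna(de_c_call, de_m_call, hits_c, hits_m, th$energy_sum_max)
  write_table(net$triples, file.path(out_dir, "triples.tsv"))
  write_network(net$edges, file.path(out_dir, "cerna.sif"), "sif")
  if (nrow(net$edges) > 0)
    write_network(net$edges, file.path(out_dir, "cerna.graphml"), "graphml",
                  node_kinds = net$node_kinds)

  ## --- stage 5: GSEA of network mRNAs -------------------------------------
  msg("GSEA")
  ranking <- data.frame(gene_id = de_m$feature_id, metric = de_m$logFC)
  net_genes <- unique(net$triples$mrna_id)
  # two probe sets: the network mRNAs (mixed directions) and the planted
  # up-regulated program, the synthetic stand-in for a curated pathway set
  tru <- scen$mrna$truth$de_features
  up_set <- tru$feature_id[tru$direction == "up"]
  gs <- list(planted_up = up_set)
  if (length(net_genes) >= 2) gs$cerna_mrnas <- net_genes
  enr <- gsea(ranking, gs, n_perm = config$gsea$n_perm,
              weight = config$gsea$weight, seed = derive_seed(seed, 5L))
  if (nrow(enr)) write_table(enr, file.path(out_dir, "gsea.tsv"))

  ## --- stage 6: PPI hubs ---------------------------------------------------
  msg("hub ranking")
  hub_scores <- mcc_scores(scen$ppi$edges, nodes = scen$ppi_nodes)
  hubs <- top_hubs(hub_scores, th$k_hubs)
  write_table(hub_scores, file.path(out_dir, "hub_scores.tsv"))

  ## --- stage 7: survival signature ----------------------------------------
  if (is.null(scen$survival)) {
    msg("no survival block; stopping after hub stage")
    return(invisible(list(de_mrna = de_m, de_circ = de_c, net = net,
                          hubs = hubs, out_dir = out_dir)))
  }
  msg("survival signature")
  surv <- scen$survival$survival
  cand <- intersect(hubs, names(surv))
  cox_tab <- do.call(rbind, lapply(cand, function(g) {
    u <- cox_univariate(surv, g)
    data.frame(gene = g, beta = u$beta, hr = u$hr, p = u$p)
  }))
  write_table(cox_tab, file.path(out_dir, "cox_univariate.tsv"))
  screened <- cox_tab$gene[cox_tab$p < th$alpha]
  if (length(screened) < 2) screened <- cand
  model <- lasso_cox(surv, screened, n_folds = config$lasso$n_folds,
                     rule = config$lasso$rule,
                     seed = derive_seed(seed, 7L))
  rs <- risk_scores(model, surv)
  lr <- if (length(unique(rs$group)) == 2)
    logrank(surv[rs$group == "high", ], surv[rs$group == "low", ])
  else list(chisq = NA_real_, p = NA_real_)
  auc <- td_auc(surv, rs$score, th$horizons)
  model$auc <- auc
  model_json <- list(genes = as.list(model$genes),
                     betas = as.list(unname(model$betas)),
                     lambda = model$lambda, cutoff = model$cutoff,
                     auc = as.list(auc), logrank_p = lr$p)
  jsonlite::write_json(model_json, file.path(out_dir, "model.json"),
                       auto_unbox = TRUE, digits = 10)
  write_table(cbind(sample = surv$sample, rs),
              file.path(out_dir, "risk_scores.tsv"))

  ## --- stage 8: signature subnetwork ---------------------------------------
  sig_seq <- intersect(model$genes, unique(net$triples$mrna_id))
  subnet <- subnetwork(net, sig_seq)
  write_table(subnet$triples, file.path(out_dir, "subnetwork_triples.tsv"))

  ## --- report and manifest --------------------------------------------------
  report <- truth_report(scen, de_m_call, de_c_call, net, hubs, model, auc, lr)
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = 10)
  manifest <- list(
    package = "cernaforge",
    version = as.character(utils::packageVersion("cernaforge")),
    seed = seed, thresholds = th, synthesis = sy,
    config_hash = config_hash(config))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = 10)
  invisible(list(scenario = scen, de_mrna = de_m, de_circ = de_c,
                 de_mrna_called = de_m_call, de_circ_called = de_c_call,
                 hits_circ = hits_c, hits_mrna = hits_m, net = net,
                 enrichment = enr, hub_scores = hub_scores, hubs = hubs,
                 model = model, risk = rs, auc = auc, logrank = lr,
                 subnet = subnet, report = report, out_dir = out_dir))
}

#' Compare pipeline output with the planted truth
#'
#' @param scen scenario from [gen_cerna_scenario()].
#' @param de_m_call,de_c_call filtered DE tables.
#' @param net ceRNA network from [build_cerna()].
#' @param hubs hub gene ids.
#' @param model fitted `RiskModel`.
#' @param auc named AUC vector.
#' @param lr log-rank result for the risk groups.
#' @return list of recovery metrics (precision/recall of DE calls and
#'   triples, hub and signature recovery, AUCs).
#' @export
truth_report <- function(scen, de_m_call, de_c_call, net, hubs, model,
                         auc, lr) {
  tr <- scen$truth
  de_true <- tr$de_features$feature_id
  de_called <- c(de_m_call$feature_id, de_c_call$feature_id)
  key <- function(d) paste(d$circ_id, d$mir_id, d$mrna_id)
  got <- key(net$triples); want <- key(tr$planted_triples)
  clique <- tr$planted_cliques[[1]]
  list(
    de = list(sensitivity = mean(de_true %in% de_called),
              false_calls = sum(!de_called %in% de_true),
              n_called = length(de_called)),
    cerna = list(
      precision = if (length(got)) mean(got %in% want) else NA_real_,
      recall = if (length(want)) mean(want %in% got) else NA_real_,
      n_triples = length(got)),
    hubs = list(clique_recovered = mean(clique %in% hubs),
                top = hubs),
    signature = list(
      genes = model$genes,
      planted = names(tr$prognostic_betas),
      recovered_all = all(names(tr$prognostic_betas) %in% model$genes),
      exact = setequal(model$genes, names(tr$prognostic_betas))),
    auc = as.list(auc),
    logrank_p = lr$p)
}

#' Read a YAML pipeline configuration
#' @param path YAML file whose top-level keys override [cerna_config()].
#' @return configuration list.
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- cerna_config(seed = if (!is.null(user$seed)) user$seed else 1)
  for (k in names(user)) {
    if (is.list(user[[k]]) && is.list(cfg[[k]]))
      cfg[[k]][names(user[[k]])] <- user[[k]]
    else cfg[[k]] <- user[[k]]
  }
  cfg
}

config_hash <- function(config) {
  s <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = 12)
  # small rolling hash; provenance fingerprint, not cryptographic
  sum_ <- 0
  for (ch in utf8ToInt(s)) sum_ <- (sum_ * 31 + ch) %% 2147483647
  sprintf("%d", sum_)
}
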