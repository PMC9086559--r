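# cernaforge

Infer circRNA–miRNA–mRNA competing-endogenous-RNA (ceRNA) networks and
downstream prognostic signatures from expression counts and RNA
sequences, with a planted-truth simulation layer that makes every stage
testable end to end.

Intended for computational biologists building or auditing ceRNA
analyses of paired tumor/normal RNA-seq: the package gives the whole
chain as composable, deterministic functions instead of a collection of
hand-glued external tools.

## What it computes

* **Quantification** — FPKM for genes, `FPKM = c / ((N/10^6)·L_kb)`, and
  SRPBM for back-splice junction reads, `SRPBM = c / (N/10^9)`; TMM
  scale factors for composition bias.
* **Differential expression** — an exact conditional binomial test on
  TMM-adjusted group sums (the Poisson limit of the exact
  negative-binomial count test) with BH correction; screening at
  `|log2FC| > 2` with adjusted p < 0.05 (mRNA) or raw p < 0.05
  (circRNA).
* **miRNA target sites** — miRanda-style seed-weighted affine-gap local
  alignment (Watson–Crick +5, G:U +1, mismatch −3, gaps −9/−4, seed
  positions 2–8 ×2; C++ kernel) plus a nearest-neighbour duplex
  free-energy estimate; sites kept at score > 140 and ΔG < −20 kcal/mol.
* **ceRNA network** — (circRNA, mRNA) pairs joined on shared miRNAs,
  kept when expression trends are synergistic (same direction) and the
  summed best-site energies fall below −90 kcal/mol.
* **Hub genes** — Maximal Clique Centrality, `MCC(v) = Σ_C (|C|−1)!`
  over maximal cliques, top-10 extraction.
* **Prognostic signature** — univariate Cox screen, LASSO-Cox selection
  (cross-validated deviance), median-split risk groups, log-rank test,
  and IPCW time-dependent ROC at 3/5/7 years.
* **Enrichment** — weighted Kolmogorov–Smirnov enrichment score with a
  gene-label permutation null; significance at |NES| > 2 and p < 0.05.
* **Synthetic data** — generators for counts, sequences, PPI graphs and
  survival tables with planted ground truth (`gen_count_matrix`,
  `gen_sequences`, `gen_ppi`, `gen_survival`, `gen_cerna_scenario`).

## Worked example

Run the full chain on the default synthetic study (8 tumor/normal pairs,
2000 genes, 300 circRNAs, 4 planted ceRNA pairs sharing 2 miRNAs each,
a planted 6-clique in the PPI, 136 patients with a 3-gene hazard):

```r
library(cernaforge)
res <- run_all(cerna_config(seed = 1), out_dir = "cerna_run")
str(res$report)
```

```
List of 6
 $ de       :List of 3
  ..$ sensitivity: num 0.974
  ..$ false_calls: int 0
 $ cerna    :List of 3
  ..$ precision: num 1
  ..$ recall   : num 1
  ..$ n_triples: int 8
 $ hubs     :List of 2
  ..$ clique_recovered: num 1
 $ signature:List of 4
  ..$ genes        : chr [1:3] "gene0016" "gene0053" "gene0019"
  ..$ recovered_all: logi TRUE
 $ auc      : 3y 0.874, 5y 0.868, 7y 0.900
 $ logrank_p: num 3.2e-18
```

Reading: 97% of planted differential features are re-called with no
false calls; all 8 planted (circ, miRNA, mRNA) triples are recovered
with no spurious ones; every member of the planted PPI clique lands in
the top-10 hubs; the LASSO-Cox signature selects exactly the three genes
that drive the simulated hazard, and the resulting risk score separates
the cohort (log-rank p ≈ 3×10⁻¹⁸) with time-dependent AUC well above
0.7 at all horizons:

```r
print(res$model)
#> RiskModel: 3 gene(s), lambda = 0.008298, cutoff = 0.04616
#> gene0016 gene0053 gene0019
#>   0.9709   1.2529   1.0985
head(res$net$triples[, c("circ_id", "mir_id", "mrna_id", "sum_max_energy")])
#>                   circ_id  mir_id  mrna_id sum_max_energy
#> 1 chr18:13715900-13717936 mir-003 gene0019        -161.44
#> 2 chr18:13715900-13717936 mir-004 gene0019        -161.44
#> 3 chr22:55478972-55522133 mir-001 gene0016        -171.92
```

The run directory holds every intermediate as plain text: count and DE
tables, target-site hits, the triple table, SIF/GraphML network exports,
hub scores, the model JSON, a truth-vs-output `report.json` and a
`manifest.json` with the configuration fingerprint. Individual stages
are available directly (`de_test`, `scan_targets`, `build_cerna`,
`mcc_scores`, `lasso_cox`, `td_auc`, `gsea`, …); a thin command-line
front end lives in `inst/cli/cerna-forge.R`.

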