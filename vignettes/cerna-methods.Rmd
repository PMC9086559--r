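---
title: "Methods: ceRNA network inference with planted-truth simulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ceRNA network inference with planted-truth simulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`cernaforge` implements a complete competing-endogenous-RNA (ceRNA)
inference chain for circRNA–miRNA–mRNA regulation: quantification and
differential expression of circRNAs and mRNAs from count tables, miRNA
binding-site prediction on both molecule classes, assembly of the ceRNA
network from shared miRNA targets, hub-gene ranking on a protein–protein
interaction (PPI) graph, and a penalised Cox risk-score signature with
time-dependent ROC evaluation. The package consumes junction-count and
gene-count tables — circRNA *detection* from raw reads, annotation
enrichment against GO/KEGG databases, and PPI database queries are out of
scope; PPI input is a plain edge list.

Because the real inputs of such studies (tumor cohorts, TARGET survival
data) cannot ship with a package, every stage is exercised against a
synthetic-data module that plants a known truth and then asks the chain
to recover it. The generators are first-class, tested code, not fixtures.

# Quantification and differential expression

mRNA abundance uses FPKM,
$\mathrm{FPKM}_{ij} = c_{ij} / \big((N_j/10^6)\,L_i\big)$, with $c_{ij}$
the fragment count, $N_j$ total mapped reads and $L_i$ exon length in kb.
circRNA abundance uses SRPBM, $c_{ij} / (N_j/10^9)$, counting back-splice
junction reads; there is no length term because each junction read spans
the same single junction.

Between-sample composition bias is handled by TMM scale factors: the
reference sample is the one whose upper quartile of depth-scaled counts
is closest to the mean upper quartile; per-feature log-ratios are trimmed
(30% on M, 5% on A), averaged with inverse-variance weights, and the
factors rescaled to geometric mean 1. The implementation is checked
against `edgeR::calcNormFactors` on random negative-binomial data.

The two-group test is an exact conditional binomial test on group-summed
counts: conditional on the feature total, the group-2 sum is Binomial
with success probability equal to group 2's share of the effective
(TMM-scaled) depth. This is the Poisson limit of the exact
negative-binomial count test; it is exact under Poisson variation and
anti-conservative under overdispersion, which is why the null-calibration
simulation in the test suite uses dispersion 0. Two-sided p values double
the smaller tail (capped at 1); log2 fold-changes use a pseudo-count of
0.5 to avoid infinities; BH correction is applied across features. The
screening rules are `|logFC| > 2` with adjusted `p < 0.05` for mRNA and
with raw `p < 0.05` for circRNA — both strict inequalities, both exposed
through `use_adjusted` because published practice is ambiguous about
which p enters the circRNA screen. A paired mode conditions within
tumor/normal pairs and combines the pair-level binomials by exact
convolution; the default is the unpaired group comparison.

# miRNA target scoring

Site prediction follows the miRanda family: the miRNA (read 3'→5') is
locally aligned to the target (5'→3') with affine gaps (Gotoh dynamic
programme, written in C++), scoring +5 for Watson–Crick pairs, +1 for
G:U wobbles, −3 for mismatches, −9/−4 for gap open/extend, and doubling
the pair/mismatch contribution at miRNA seed positions 2–8. A perfect
22-nt complement therefore scores $5 \times 15 + 10 \times 7 = 145$. The
published thresholds — alignment score > 140 and duplex energy
< −20 kcal/mol — are the defaults; the scoring matrix itself is not
published with those thresholds, so all parameters sit in `mir_params()`.

Duplex stability is estimated from the alignment alone: a sum of
nearest-neighbour stack free energies (the standard published
Watson–Crick ΔG°37 table, embedded) over runs of consecutive paired
columns, plus a +4.09 kcal/mol initiation term. Stacks involving a G:U
wobble take a flat −1.0 kcal/mol; terminal-AU penalties and full
secondary-structure folding are deliberately omitted — the chain only
thresholds a duplex ΔG, and the simplification keeps the estimate
deterministic and self-contained. Note the consequence: an all-A/U
helix of 22 nt sits near −15 kcal/mol and would *fail* the −20 screen;
random-composition sites pass with huge margin (≈ −40).

`scan_targets()` slides a window (miRNA length + 12 nt, stride 6) along
each target, applies both thresholds, and resolves overlaps greedily by
descending score with leftmost tie-break, so output is deterministic and
order-independent. The aligner is validated against an exhaustive
memoised suffix-recursion oracle on 200 random short instances, and a
Monte-Carlo null (random 22-mers vs random 1-kb targets over 20 seeds)
confirms that the default thresholds admit essentially no background.

# ceRNA network assembly

For each (circRNA, mRNA) pair of differential features, the shared miRNA
set contains miRNAs with at least one retained site on both molecules. A
pair enters the network iff (i) the shared set is non-empty, (ii) the
expression trends are synergistic — both up or both down, per the sponge
logic: a circRNA that soaks up a miRNA de-represses its mRNA targets —
and (iii) the energy sum is strictly below −90 kcal/mol. The energy sum
is read as: per shared miRNA, take the most negative site energy on each
molecule, then sum both values across all shared miRNAs at the pair
level. Of the plausible readings of "sum max energy" this is the one
that matches a sum of per-interaction best energies; it is configurable
via `energy_sum_max` and the aggregation is isolated in `build_cerna()`.
One consequence worth knowing: a pair sharing a single miRNA with one
perfect 22-nt site on each side sums to ≈ −80 and is *excluded*; the
planted scenario therefore gives each true pair two shared miRNAs.

Hub ranking uses Maximal Clique Centrality:
$\mathrm{MCC}(v) = \sum_{C \ni v} (|C|-1)!$ over maximal cliques $C$,
so an isolated node scores 1. Enumeration is Bron–Kerbosch with pivoting
(via igraph) behind a configurable budget; ties in the ranking break
lexicographically. A subset-enumeration oracle checks MCC exactly on
random graphs with up to 12 nodes.

# Survival signature

Kaplan–Meier curves, the two-group log-rank test and univariate Cox fits
wrap the survival package (Breslow tie handling; Wald inference). The
signature is built the way the source analyses do: univariate Cox
screening of the hub genes at p < 0.05, then LASSO-penalised Cox on the
survivors with the penalty chosen by 5-fold cross-validated
partial-likelihood deviance. The minimum-deviance rule is the default
(the 1-SE rule is available); fold assignment is controlled by the seed
argument. The risk score is the linear predictor
$\sum_i \beta_i x_i$; patients strictly above the training-median score
are "high risk", ties go low — a deterministic convention for discrete
data.

Time-dependent ROC uses the cumulative-case / dynamic-control definition
with inverse-probability-of-censoring weights from the Kaplan–Meier
estimate of the censoring distribution; tied scores count ½, so a
constant score gives AUC 0.5 by convention. Horizons default to 3, 5 and
7 years. No pre-installed package provides this estimator, so it is
implemented directly and checked against its closed-form extremes
(perfect predictor → 1.0; random scores → 0.5 ± 0.05 at n = 1000).

# Enrichment statistic

The GSEA statistic is the weighted Kolmogorov–Smirnov running sum: hits
add $|r|^w$ normalised by the in-set total, misses subtract
$1/(N-N_\mathrm{set})$; the ES is the extreme deviation, always in
[−1, 1]. The null is gene-label permutation — random same-size sets —
rather than phenotype permutation: the module consumes a precomputed
ranking (logFC by default) and desk-scale inputs, and this is a
documented deviation from sample-permutation GSEA. NES divides the ES by
the mean |null ES| of matching sign, and the p value is the add-one
estimate against same-sign nulls, which is uniform under the null and
never below $1/(1+n_\mathrm{perm})$. Significance follows the
|NES| > 2 and p < 0.05 rule.

# The synthetic study and what it does (not) show

`gen_cerna_scenario()` composes one coherent study from one seed:

* **Counts** — negative-binomial (gamma-Poisson), the model the
  edgeR-style workflow assumes: 2000 mRNA and 300 circRNA features over
  8 tumor/normal pairs (the paired design of the emulated study), 5% of
  features planted differential at fold-change 6 (direction split
  50/50), dispersion 0.1, library sizes 2×10⁷ (mRNA) and 5×10⁷
  (junction reads). Fold-change 6 keeps the planted |log2FC| ≈ 2.58
  clear of the strict >2 screen under sampling noise.
* **Sequences** — uniform random RNA backgrounds with exact
  reverse-complements of full 22-nt miRNAs embedded at recorded,
  non-overlapping positions; 4 planted (circ, mRNA) pairs sharing 2
  miRNAs each, plus decoy sequences mapped to non-differential features.
* **PPI** — all edges of a planted 6-clique containing the 3 signature
  genes, plus 40 random noise edges over ~34 candidate genes.
* **Survival** — 136 patients (the size of the emulated external
  cohort); event times exponential with hazard
  $\propto \exp(\sum \beta x)$, β = 1 on the three signature genes over
  standard-normal expression, uniform censoring calibrated to 30%.

Everything is seed-deterministic; re-running a generator or the whole
pipeline with one seed reproduces outputs byte-for-byte.

What this does **not** emulate: realistic GC/repeat structure or folding
accessibility of transcripts, partial (seed-only) miRNA sites, correlated
expression between the tumor matrix and the survival cohort, clinical
covariates, or batch structure. Passing the recovery suite therefore
shows the chain is *correct under its stated model*, not that the
thresholds are well-calibrated for any particular real cohort.

# Numerical choices and edge cases

* All screening inequalities are strict, matching the published wording;
  boundary tests pin this down (logFC = 2 excluded, energy sum = −90
  excluded).
* Tie-breaks are lexicographic everywhere ranked output is produced;
  overlap resolution in site scanning is greedy by score then position.
* The alignment traceback prefers the earliest (leftmost-topmost) best
  cell, making reported positions deterministic.
* Degenerate inputs error early with named offenders: all-zero samples
  in TMM, non-ACGU characters, constant expression in a median split,
  cliques smaller than 2, censor rates outside [0, 1).
* Problem sizes in the test suite (5000-feature calibrations, n = 2000
  Cox consistency, 50-seed LASSO recovery, 200-instance alignment
  oracle) were chosen as the smallest sizes at which the asymptotic
  claims they test are expected to hold with comfortable margin.

# Known limitations

The DE test is a Poisson-limit approximation: with strong overdispersion
its raw p values are anti-conservative, and the |logFC| > 2 screen is
what keeps the false-call rate low in the planted simulations. The
energy model ignores loops, bulge geometry and terminal effects. MCC is
exponential in the worst case and guarded only by a budget. The LASSO
path and fold assignment follow glmnet's conventions; exact selected
sets can differ across glmnet versions even at a fixed seed.
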