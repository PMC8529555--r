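---
title: "Cross-cohort co-expression modules: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-cohort co-expression modules: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coexmod)
```

coexmod implements a multi-cohort transcriptomics workflow built around gene
co-expression networks (GCNs): per-cohort network construction, module
detection, cross-cohort module conservation, module topology, gene-set and
transcription-factor over-representation, reporter-feature scoring, and
expression-based survival prognosis. This vignette explains the models and
the numerical choices; the README shows the happy path.

## Network construction

Within each cohort, genes whose median TPM falls strictly below 1 are
removed (`filter_low_expression()`; the summary statistic is switchable to
the mean via `tpm_filter_stat` — both conventions appear in practice and the
choice is recorded in the network's provenance). All remaining gene pairs
are scored with Spearman's rank correlation (midranks for ties; exact
permutation p-values for 9 or fewer samples, the t approximation otherwise),
p-values are BH-adjusted **over all tested pairs**, and the network retains
the positively correlated pairs at FDR < 0.05 — and of those only the top
10% ranked by rho (`top_edge_fraction`). Ties at the retention cutoff break
by smaller p, then lexicographic pair id, so the edge set is deterministic.
Spearman makes the whole construction invariant under any strictly
increasing per-gene transform, which is why the synthetic generator is free
to work on log2 scale.

Two decisions here were genuinely open:

* *Where BH is applied.* Adjusting over all pairs (rather than only positive
  ones) follows the convention of adjusting every test performed; the
  positive-rho restriction is applied to the adjusted results.
* *What "top 10%" ranks.* We rank the FDR-significant positive pairs by rho
  and keep the top decile — the alternative (a rho quantile over all pairs)
  is not expressible as a fraction of *significant* pairs. The rule is
  stored in the provenance so results are auditable.

The screen's behaviour depends on the correlation landscape: when moderate
correlations dominate the significant-positive pool, strongly co-expressed
modules pass the decile cut almost intact while their weakest internal pairs
are pruned, which is what gives modules hub structure.

## Module detection and conservation

Modules are communities under modularity maximisation: Leiden with the
resolution-free modularity objective on the unweighted retained edges
(`detect_modules()`; Louvain is available behind the same contract).
Communities smaller than `min_module_size = 30` genes are reported as
unassigned rather than merged. Surviving modules are relabelled 1..K by
decreasing size, so labels are stable and the relabelling is idempotent.
One integer seed (`rng_seed`) fixes community-detection randomness; the test
suite uses structures with unambiguous optima because library versions can
legitimately differ on marginal splits.

Conservation between cohorts is measured per module pair by the Jaccard
index and an upper-tail hypergeometric test (observed overlap included in
the tail). The test universe defaults to the intersection of the two
cohorts' post-filter gene sets — the genes eligible to co-occur — and is
configurable (union, or a fixed count) because published analyses rarely
state it; printed hypergeometric p-values are therefore not comparable
across universe conventions, while Jaccard indices are. Consensus modules
are maximal cliques (one module per cohort) in the graph of significantly
overlapping pairs, with the consensus gene set the intersection of members:
this mirrors the pairwise procedure rather than any simultaneous multi-set
test.

## Topology

Degree and closeness centrality are computed on the module-induced subgraph,
with closeness normalised per connected component,
`(n_c - 1) / sum of distances`, so cliques score exactly 1 and isolated
nodes 0 (no harmonic fallback). The full-network degree is carried as a
secondary column. Cross-cohort degree concordance is the Spearman
correlation of within-module degree over the genes two modules share; it is
undefined (and an error below 3 shared genes) when either degree vector is
constant — which is itself a signal that a module survived as a complete
clique.

## Enrichment and reporter features

Over-representation uses the same hypergeometric tail with BH correction
within one collection per query. Every set is intersected with the
background first; the background policy (network genes, union of detected
modules, or a user list) is explicit and recorded, because enrichment
p-values are meaningless without it. TF enrichment treats each regulator's
target set as a gene set.

Reporter scoring aggregates gene-level DE evidence onto bipartite features
(metabolites via a gene–metabolite table from a genome-scale metabolic
model, or TFs via TF–target relationships). Gene p-values become
`z = qnorm(1 - p)` (clamped to `[1e-15, 1 - 1e-15]`); a feature with k
scored neighbours gets `z_raw = sum(z) / sqrt(k)`, standardised against the
empirical mean and s.d. of `z_raw` over `reporter_background_samples`
(default 10,000) random k-subsets of all scored genes, cached per k and
seeded. Sampling from the *scored* genes rather than the genome keeps the
null conditional on the realised p-value distribution. Directional lists
("up" / "down" reporters) come from re-running with opposing genes' p-values
reset to 1, and module-specific reporter TFs from masking genes outside the
module to p = 1 — both are subset-masking simplifications of multi-class
directionality, chosen because exactly two directional lists are wanted.
If every scored gene carries the same p the background is degenerate; the
score is then exactly central (z = 0, p = 0.5) rather than an error, since
the feature cannot deviate from a constant background.

## Survival prognosis

`km_estimate()` is the product-limit estimator (via the survival package);
`logrank_test()` implements the standard two-group log-rank from the
observed/expected decomposition with hypergeometric variance, returning O
and E for the high group — it is verified edge-for-edge against
`survival::survdiff()` in the tests, and exists as its own routine because
the cutpoint scan calls it thousands of times. `cutoff_scan()` tries every
distinct expression value within the 20th–80th percentile band as a
cutpoint (strict `>` defines the high group; tie on minimum p breaks toward
the cutpoint nearest the median), keeps the minimum-p cutpoint, and labels
the gene unfavourable when the high group's observed events exceed its
expected events. Genes enter the scan only with mean TPM > 1.

**No multiple-testing correction is applied across cutpoints or genes** —
deliberately, to match the procedure as practised. The selected p-values
are therefore optimistic: under a null with expression independent of
survival (200 genes, 200 samples, ~60% events), the scan flags roughly
30–35% of genes at nominal α = 0.05, in line with optimal-cutpoint theory,
while a fixed median split is calibrated at 5%. Downstream users should
treat "prognostic" flags as screening calls, not inference.

## The synthetic generator

`synthetic_design()` / `generate_cohorts()` emulate the multi-cohort
structure the pipeline assumes, on a latent-factor log-normal model (the
pipeline's Spearman statistics are invariant to monotone transforms, so the
marginal family is irrelevant — only the correlation structure matters):

* three cohorts of 150, 75 and 60 samples (echoing a 215/75/58 study layout
  at tractable compute) with control/NAFL/NASH groups in proportions
  0.2/0.3/0.5;
* one 60-gene disease module shared by all cohorts: gene g's log2
  expression is `baseline + loading_g * f + shift_g(group) + N(0, 0.3)`
  with a per-cohort latent factor f and per-gene loadings drawn once from
  U(0.4, 0.95) and reused in every cohort — hub identity is conserved, and
  the group shift scales with the loading (module average +1 log2FC in
  NAFL, +1.5 in NASH), so hubs are also the most disease-responsive;
* one 45-gene cohort-specific module per cohort (same loading scheme, no
  group shift); the genes exist in every cohort but are only co-regulated
  in their own, emulating a shared genome with cohort-specific structure;
* 400 background genes in four weakly correlated blocks (Spearman ≈ 0.45):
  the broad moderate co-expression of real transcriptomes. This pool is
  what the top-decile screen competes against; without it, the decile cut
  falls inside the strong modules and shreds them, which is not the regime
  the screening rule was designed for;
* 50 genes planted below the TPM-filter floor, to exercise the filter;
* a bipartite feature map whose concentrated fraction (default 25%) draws
  targets from the disease module, the rest uniformly;
* survival times exponential with rate
  `0.002/day * exp(sum beta_g z_g)` on standardised log2(TPM+1), with
  independent exponential censoring at 0.0015/day (≈ 55–60% events);
  defaults place +1 on a disease-module gene and −1 on a background gene,
  deliberately uncorrelated so neither effect masks the other.

Each generator call seeds its own RNG stream from the design seed plus a
stage tag, so stages are reproducible in isolation and bitwise-identical
under a repeated call.

What the generator does **not** emulate: RNA-seq count noise (negative
binomial sampling, library-size artifacts), batch effects, outlier samples,
or gene-length effects. Passing tests on this generator show the pipeline
recovers planted correlation structure and calibrated nulls — they do not
certify behaviour under count overdispersion or batch confounding, which
real data preprocessing must address upstream.

## Differential expression

The built-in `compute_de()` is a two-sided Wilcoxon rank-sum on
log2(TPM+1) — exact for group sizes ≤ 10 without ties, normal approximation
with tie correction otherwise — with fold changes computed on mean TPM with
pseudocount 1 and BH adjustment across genes. This deliberately does not
reproduce negative-binomial DE models (no dispersion estimation or size
factors); the role of the stage is to supply (log2FC, p) semantics to the
reporter and module-perturbation logic, and `import_de_table()` accepts any
external tool's per-gene output where fidelity to a specific DE model
matters.

## Problem sizes and determinism

Default test and example sizes (three cohorts of ≤ 150 samples, ~700 genes,
~240k correlation pairs per cohort; 500-feature reporter nulls at 10,000
background draws; 50-replicate survival power runs at n = 300) were chosen
so the whole pipeline runs in minutes on a single core while keeping every
statistic in its asymptotic regime. All stochastic steps flow from explicit
integer seeds; `run_pipeline()` derives per-stage sub-seeds by stable
hashing so re-running any stage in isolation reproduces its output, and the
run record stores MD5 checksums of every artifact.

## Known limitations

* The edge screen's "top 10%" is relative to the significant-positive pool:
  on very small or very weakly correlated datasets the retained graph can
  be too sparse for stable community detection.
* Hypergeometric overlap p-values depend on the universe convention; only
  Jaccard indices are directly comparable across studies.
* The cutpoint scan's selected p-values are optimistic (see above).
* Reporter directionality via subset masking does not model mixed
  (distinct-directional) regulation of one feature's neighbourhood.
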