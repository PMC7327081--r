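---
title: "Staging tumours by single-sample co-expression perturbation: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Staging tumours by single-sample co-expression perturbation: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(coexstage)
```

## The model

`coexstage` stages a tumour sample by how consistently it fits the
co-expression structure of each stage. The underlying assumption is
that cancer samples of the same stage share stage-specific co-expressed
gene programs: when a sample is added to a reference cohort of its own
stage, pairwise correlations among that stage's signature genes barely
move; added to another stage's cohort, its expression is not linearly
consistent with that cohort's programs and many edge correlations
collapse.

The pipeline is four steps per run.

**Stage-specific DEGs.** For each stage versus control the built-in
screen is Welch's two-sample t-test on log₂ expression with the log₂
fold change as the difference of group means; a gene qualifies when
|log₂ FC| > 2.5 and p < 0.05, both strict inequalities. No multiplicity
correction is applied at this screen — it feeds a second, much stricter
filter (the network threshold), and correcting here would only shift
the operating point of an intermediate step. An external DE table (for
example from a count-based negative-binomial pipeline) can be imported
and is pushed through identical thresholds, so the DE engine is
pluggable without touching anything downstream. Because the four stage
cohorts differ in size, each stage keeps only its *n* highest-variance
DEGs, with *n* the minimum DEG count over stages; variance is computed
over the stage's cancer samples, and exact ties break by gene
identifier so runs are reproducible.

**Reference networks.** Each stage's samples split 30/40/30 into
reference, training and test sets (floor for reference and test, the
remainder to training, which benefits most from extra samples). Over
the reference samples, every selected DEG pair with |ρ| > 0.7 and
t-based p < 0.05 (t = ρ√(n−2)/√(1−ρ²), df = n−2) becomes an edge.
The edge list is stored in lexicographic order; that order is the
immutable feature layout.

**Perturbation vectors.** For a new sample, each edge's correlation is
recomputed over reference ∪ {sample}. Entries are the recomputed ρ for
retained edges (|ρ| still above 0.7) and exactly 0.0 for removed ones.
Two design choices deserve note. First, we store the *expanded-set*
correlation rather than the reference value: the reference value is
constant across query samples and would carry no per-sample signal.
Second, the layout is fixed to the reference edges; candidate pairs
that only become correlated after adding the sample are not appended,
because a classifier needs every sample to live in the same feature
space. An `all-pairs` layout that scores every selected-DEG pair
(zeroing those at or below threshold) is available for users who want
edge gains represented too. Significance is not re-tested on the
expanded set — one added sample changes n by one and the p-cut would be
nearly redundant next to the threshold relation.

**Classification and evaluation.** The concatenated four-block vector
feeds a 4-way classifier chosen from a registry: gradient-boosted trees
(default), bagged trees, random forest, a variance-weighted-subspace
forest, an extremely-randomized shallow-tree ensemble standing in for
random ferns, and Gaussian naive Bayes. Hyperparameters are selected by
stratified 3-fold cross-validation repeated (100 repeats by default)
maximizing overall accuracy, then the winner is refit on all training
samples. Test-set results are summarized as a predicted-by-annotated
confusion matrix, one-vs-rest sensitivity and specificity per stage,
accuracy, and Cohen's kappa (p₀ − pₑ)/(1 − pₑ) with pₑ from the
marginal products. The whole pipeline repeats for a configurable number
of outer iterations (default 10) with derived seeds, and metrics are
reported as mean ± sd across iterations.

## Pair-level pathway enrichment

Gene-set enrichment is computed over *pairs*, not genes: with N DEG
pairs of one regulation direction and K of them co-expressed, a pathway
contributing n DEG pairs of which k are co-expressed is scored by the
hypergeometric upper tail P(X ≥ k) under (N, K, n). We use the upper
tail rather than the point mass P(X = k) because a point probability is
not a significance level — it vanishes for every k as N grows — but a
`point_mass` mode is kept for compatibility with pipelines that score
by the single term. Across a pathway collection, Benjamini–Hochberg
adjustment at α = 0.05 is the default (raw-p mode available); an
enrichment screen over hundreds of gene sets without multiplicity
control mostly measures collection size.

Comparing enriched sets between control and the four stages, each
control-enriched pathway is classified as **persistent** (enriched in
control and all four stages), **disappeared at stage s** (enriched in
control and every stage before s, absent from s onward), or
**intermittent** (any non-monotone pattern). The prefix condition for
disappearance — enriched at every earlier stage — is our reading of
"disappears by stage s and does not appear again"; the intermittent
bucket keeps the three categories an exact partition of the
control-enriched set, which is asserted in the tests. Pathways absent
in control are **emergent**, split into early (enriched at stage 1
or 2) and advanced (stage 3 or 4).

## The simulator

`simulate_staged_expression()` generates the statistical structure the
method presumes, with known ground truth. Each stage owns
`modules_per_stage` modules of `module_size` genes. For samples of the
owning stage, module gene g is

x_g = μ + d_g + σ·(s_g·√ρ·f + √(1−ρ)·ε),

with f a per-sample latent factor shared within the module, s_g = ±1 a
random loading sign, d_g = ±`de_effect_logfc` a random DE shift, σ =
`noise_sd`, and ρ = `within_module_correlation` the exact population
|PCC| between module genes. Elsewhere (controls, other stages,
non-module genes) values are independent baseline noise, so planted
DEGs and planted edges are unambiguous.

Loading signs and DE directions are drawn independently, and this is
deliberate: if every module gene rose by the same shift with
all-positive loadings, a wrong-stage sample would sit on the major axis
of every reference edge cloud and co-expression would *not* be
disrupted — the staging signal would vanish. Independent signs make a
wrong-stage sample's deviation vector misaligned with roughly half the
edges, which is the disruption mechanism the method relies on; samples
of the owning stage are ordinary draws from the reference distribution
and keep nearly all edges. With `shared_modules = TRUE` all four stages
receive identical modules, shifts and loadings, making the four cancer
groups statistically identical — the negative control under which
classification must fall to chance.

Defaults mirror the study conditions used throughout the tests:
300 genes, 60 samples per group (control plus four stages), two
15-gene modules per stage, ρ = 0.9, |log₂ FC| = 3. Where no condition
was prescribed we fixed values once at what is realistic for log-scale
RNA-seq: residual sd 0.5 and baseline mean 7 on the log₂ scale. What
the simulator does *not* emulate: count-level sampling noise
(negative-binomial dispersion), library-size variation, batch effects,
correlated noise between modules, or sub-stage heterogeneity. Passing
tests on these data show the pipeline recovers planted structure under
its own assumptions; they do not certify accuracy on real cohorts,
where signal strength and confounding are far less favourable.

## Numerical choices and degenerate inputs

- Correlations and fold changes are computed on log₂ expression;
  integer count input is detected and converted to log₂(CPM + 1)
  (override with `scale=`). Correlation on raw counts is dominated by
  library size.
- All four cutoffs (fold change, DEG p, τ, edge p) are strict
  inequalities.
- A gene constant across a reference set is dropped from the node set
  with a message; a gene constant in both DE groups is skipped; a
  constant query-sample expansion that makes an edge correlation
  undefined scores the edge as removed (0.0).
- Missing values are never imputed — any NA in an expression matrix is
  a hard error at the boundary.
- Variance ties in DEG balancing and correlation ties at thresholds
  resolve deterministically (identifier order; strict comparisons).
- One master seed derives all per-iteration and per-module seeds, so a
  protocol run is reproducible from a single integer.
- By default DEG identification and variance ranking use all of a
  stage's samples — differential expression established on the full
  cohort before splitting — which lets test-sample variance influence
  gene selection. `strict_split = TRUE` restricts both to reference +
  training samples for a leakage-free variant.

## Problem sizes in the test-suite

The suite and the acceptance script run the full protocol on the
default simulation (300 genes, 4 × 60 cancer + 60 control samples) with
2 outer iterations and 3-fold × 10-repeat CV, which keeps a complete
end-to-end run at roughly a minute while leaving every stage of the
pipeline exercised at realistic dimensions; oracle checks (permutation
p-values at n = 10, exhaustive hypergeometric enumeration at N ≤ 12,
formula checks on random confusion matrices) are sized to be exact or
Monte-Carlo-tight. The permutation comparison uses a 0.02 absolute
band: three Monte-Carlo standard errors at the larger p plus an
allowance for the discreteness of the permutation distribution at
n = 10.

## Known limitations

- The six classifier backends are analogs, not re-implementations, of
  the classical learners they stand for (C5.0, treebag, WSRF, rFerns);
  results are comparable in role, not bit-identical in algorithm.
- The built-in DE screen is a Welch t-test on log-scale values, not a
  count model; for count-level fidelity import an external DE table.
- Perturbation cost is O(edges) per sample per network with a dense
  correlation recomputation; adequate at signature scale (tens of
  genes, thousands of edges), not tuned for whole-transcriptome
  networks.
- Stage networks need at least 3 reference samples and non-degenerate
  genes; very small stages (< 4 samples) cannot be split 30/40/30.
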