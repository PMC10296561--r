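---
title: "Methods: models, parameters and design choices in stromacall"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in stromacall}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`stromacall` characterizes a stroma-rich (mesenchymal, MES) expression
subtype of high-grade serous ovarian cancer and nominates causal upstream
targets of its transcriptional program. This vignette documents the models
behind each stage, the parameters that matter, what the synthetic world
does and does not emulate, and the design decisions taken where the design
was genuinely open. It states no empirical result that the test suite does
not itself compute.

## Subtyping and congruence filtering

Samples are classified into MES/IMR/DIF/PRO independently by (i)
correlation of each sample's expression with per-subtype centroid profiles
(Spearman by default; robust to monotone batch distortions) and (ii) the
mean z-scored expression of per-subtype signature genes. The scientific
content is not the classifiers — both are transparent, replaceable
backends and real centroids/signatures can be supplied as files — but the
*congruence filter*: only samples with identical labels from all
classifiers are retained as "ideal subtype representations". This filter
trades cohort size for label purity; on heterogeneous cohorts it discards
mixed-signal samples rather than forcing a call.

Numerical conventions: argmax ties break to the canonical order MES, IMR,
DIF, PRO; printed shares are count/total × 100 rounded half-up to one
decimal (base R's round-half-even would disagree with conventional cohort
tables); `consensus_filter` can never retain a sample with any classifier
disagreement (asserted by tests).

## Moderated differential expression

Two-group contrasts use an empirical-Bayes moderated t. Per gene, the
pooled variance s² (d = n₁+n₂−2 df) is shrunk toward a prior fitted by
method of moments on log s²: with e = log s² − ψ(d/2) + log(d/2), solve
ψ′(d₀/2) = Var(e) − ψ′(d/2) for the prior df d₀ (trigamma inversion by
Newton iteration) and set the prior variance from the mean of e. The
posterior variance is s̃² = (d₀s₀² + d·s²)/(d₀+d) and the moderated t has
d₀+d df. When Var(e) does not exceed ψ′(d/2), d₀ = ∞ and all genes share
s₀² — the correct limit for homoscedastic data. A cohort in which *every*
gene has zero within-group variance is degenerate and raises an error;
`pairwise_tf_nes` catches exactly that case (it arises in noise-free
simulations) and ranks genes by the plain difference of means instead,
which induces the same ordering in that regime. The test suite
cross-checks the moderated t against limma on a random fixture.

## Gene set enrichment

Preranked GSEA uses the weighted running sum: hit increments |r|^w
(normalized over the set, w = 1 by default as in common practice,
config-exposed), miss decrements 1/(N − n_set), ES the extreme deviation.
An exact positive/negative tie of the two extremes resolves to the
positive one — ties cannot occur with continuous statistics but make the
statistic implementation-stable on discrete fixtures. The null permutes
gene labels with a seeded RNG; NES divides ES by the mean |null ES| of
matching sign, and p-values use the matching-sign tail with the +1
correction. Multilevel/adaptive permutation schemes are deliberately not
used: at desk scale, plain gene permutation estimates the same quantity
with simpler semantics. Sets overlapping the signature by fewer than 3
genes are skipped with a log entry.

Single-sample GSEA follows the weighted-ECDF form: per sample, genes are
ranked by expression, rank weights are rank^α with α = 0.25, and the score
sums the difference between the weighted in-set ECDF and the unweighted
out-of-set ECDF. Sets without overlap give NA, never zero — a zero would
masquerade as a mid-range score. Cell-type scoring is reduced to ssGSEA
over supplied signatures; spillover compensation between closely related
cell types (as done by dedicated deconvolution suites) is out of scope and
flagged here so users do not over-read cross-type contrasts.

## Compartment assignment

Cells are scored against epithelial/stromal/immune signatures with module
scores: signature mean minus the mean of `n_ctrl = 50` control genes drawn
per signature gene from its average-expression bin (`n_bins = 25`,
rank-based bins for even occupancy; draws are seeded). Bin-matching
removes the expression-depth component that a naive signature mean would
carry. Scores are z-normalized per sample — the cohorts the pipeline
emulates were normalized per sample, and pooling samples would let one
sample's composition distort another's z-scores; a global option exists.
Assignment is by argmax z with deterministic tie order epithelial < immune
< stromal. A signature with constant scores within a sample has no z-score
and raises an error naming the signature.

## Ligand–receptor consensus

Subclusters with fewer than 5 cells are removed. Each (sender, receiver,
ligand–receptor) triple is scored three ways: mean-expression magnitude
(receptor complexes use the minimum subunit mean — the conservative
convention, since a complex is limited by its scarcest subunit), defined
only when ligand and every subunit are detected in ≥10% of the respective
subcluster; a cluster-label permutation p-value of that magnitude (1000
seeded shuffles, +1-corrected); and specificity (product of sender's share
of total ligand expression and receiver's share of total receptor
expression). The three scorers cover magnitude, significance and
specificity — the three axes the published multi-tool consensus spans —
while the part that defines the downstream filter, robust rank
aggregation, is implemented faithfully: per-method ranks (best = 1,
missing scores take the *worst* rank so an NA can never promote an
interaction), normalized; ρ = minₖ BetaCDF(r₍ₖ₎; k, M−k+1) over the sorted
ranks; aggregated rank = min(ρ·M, 1); significance at aggregated rank
< 0.05.

"Unique interactions per major cell type" counts distinct (ligand,
receptor) pairs in which the type participates on either side; the
sender-side-only reading is available via `unique_by = "sender"` (the
dedup key is not standardized in the field).

## Ligand activity and target enrichment

A ligand's activity on a program is the Pearson correlation between its
regulatory-potential row and the program's 0/1 membership indicator over
the gene universe; candidate ligands are removed from the gene set first
(a ligand must not predict itself). Stability comes from 5 rounds of
5-fold cross-validation in which each held-out fold is relabeled
non-member. The regulatory-potential matrix is an *input* (synthetic or
user-supplied); constructing it from signalling-network diffusion is out
of scope. Per-gene prediction scores across the top 10 ligands use the
max (matching the "most strongly predicted" reading; mean available);
"top-predicted" genes exceed the universe's 95th-percentile score
strictly, so a tied block at the quantile falls outside. Enrichment uses
the two-sided Fisher exact test with the standard convention (sum of
hypergeometric point probabilities ≤ the observed table's, with a 1+1e−7
relative guard against floating-point misses). The gene universe (all
genes vs expressed-in-tumour genes) is config-exposed; the default is the
potential matrix's own universe.

## TF activity

Regulons need ≥10 targets after intersecting with the data. Genes are
rank-transformed to normal quantiles qᵢ = Φ⁻¹(rankᵢ/(N+1));
ES = Σ modeᵢ·qᵢ/√n. The naive claim "ES is standard normal under random
target positions" ignores sampling without replacement from a finite
quantile population: Var(ES) = σ_q²(nN − M²)/(n(N−1)) with M = Σ modeᵢ and
σ_q² the population variance of the quantiles. NES = ES/sd(ES) is
therefore an *exactly* calibrated z at any universe size — the package
deviates from the simpler ES-as-NES formulation precisely so that the
calibration criterion (|NES − permutation z| ≤ 0.1) holds, and because
downstream causal inference consumes |NES| as a measurement weight, where
mis-calibration would bias network size. Rank-basedness makes NES
invariant under monotone transforms of the signature; negating the
signature negates every NES exactly, so reciprocal contrasts are exact
negations. Three-tailed enrichment variants, interaction-likelihood
weights and pleiotropy correction are intentionally omitted: only the
signed NES is consumed downstream.

## Causal contextualization

The prior-knowledge network keeps directed signed edges confirmed by ≥3
independent sources; entries annotated as both stimulating and inhibiting
are split into two edges; self-loops are dropped. Given measurements
(sign(NES), |NES|) for the top 100 TFs and a candidate list (kinases), the
solver minimizes

  Σ_m w_m·1[state(tf_m) ≠ sign_m] + β·#{active nodes} − λ·Σ reward

over states {−1, 0, +1}, subject to every active non-candidate node having
at least one active incoming edge with source-state × edge-sign equal to
its own state, and the support structure being acyclic. β = 0.9 (strict
node penalty, favouring reproducible, small networks); λ = 0.1 is chosen
small so optional pathway rewards break ties without overriding
measurements; edge-count penalties are folded into the node term.
Acyclicity and support are enforced constructively: active nodes must be
addable one at a time starting from active candidates through
sign-consistent edges — this is equivalent to the layered-ordering ILP
encoding and correctly rejects mutually-supporting cycles.

No MILP library is available in the supported environment, so the `"ilp"`
backend is an exact depth-first branch-and-bound (admissible bound:
accumulated cost minus the maximum remaining reward; nodes branched in
topological order, making the incremental support check complete for
acyclic components) and `"exhaustive"` is a vectorized full enumeration
used as its oracle. Both restrict the network to the forward closure of
the candidates (nothing outside it can be active; unreachable measured
TFs contribute constant mismatch), decompose it into weakly connected
components, and apply identical deterministic tie-breaking among
co-optimal solutions: fewest active nodes, then lexicographically smallest
active node set. Determinism here is not cosmetic — the consensus step
intersects solutions across contrasts, and an arbitrary choice among
optima would make target calls irreproducible.

Consensus calling: for each contrast X, a node active with state s in
MES_vs_X is reciprocal-consistent if the X_vs_MES solution has it at −s or
absent (nodes found in only one direction are kept by default;
`single_direction = "strict"` drops them — the treatment of one-sided
nodes is not standardized); the same nonzero state in both directions is
contradictory and excluded. The consensus is the three-way intersection of
(node, mode) pairs — the stricter reading of "intersection of all pairwise
results" — minus the measured TFs.

## The synthetic world

`make_resources()` builds a stated world, not a tunable dial: 2000
background genes; 60 regulons of 20 signed targets (75% activating); a
layered acyclic kinase → intermediate → TF network (25 kinases, 50
intermediates, ~15% inhibitory edges, evidence counts 3–8 plus
low-evidence decoys that the ≥3-source filter must remove) in which every
intermediate has one kinase parent and every TF one intermediate parent,
so planted-sign propagation is unambiguous; 2 planted kinases per subtype;
40 ligands/30 receptors (some two-subunit complexes) with 3 planted
ligands from each of two stromal/myeloid sender subclusters toward the
tumour subclusters; a regulatory-potential matrix whose planted rows
concentrate on the mesenchymal hallmark genes that those ligands actually
shift in tumour cells; and hallmark sets in which the mesenchymal program
contains genuinely up-shifted genes while decoy sets draw from unshifted
genes.

Bulk cohorts are generated directly on log2 scale (baseline N(7, 1) per
gene, shifts of 1 log2 unit, Gaussian noise sd 0.5) because every bulk
stage consumes log2 intensities; the single-cell matrix uses a log-normal
rate plus Poisson count layer and log2(1 + CP10K) normalization because
ligand–receptor scoring conventions assume normalized counts. Effect size
and noise defaults are chosen so recovery is reliable but not trivial and
are config-exposed; they were fixed before the acceptance thresholds were
measured and are not revisited. The defaults for cohort sizes (25 samples
per subtype, 50 cells per subcluster) mirror a mid-sized expression cohort
and a modest dissociated-tumour experiment.

What the generator does **not** emulate: scRNA-seq dropout/batch
structure, doublets, ambient RNA, cohort-level batch effects, correlated
gene-gene noise, or the marginal distributions of any real cohort. A green
test therefore establishes that the *algorithms* recover a planted signal
of realistic size under iid noise — not that the pipeline's biological
conclusions transfer to any particular dataset. Because the generated
prior network is acyclic by construction, the solver's cycle handling is
exercised by dedicated cycle fixtures in the tests, not by the generator.

## Numerical and interface choices

* Seeds: every stochastic operation takes an explicit seed and restores
  the caller's RNG state; the pipeline fans one master seed out to stages
  by fixed offsets so stages can be rerun in isolation.
* Config files are JSON (no YAML parser is guaranteed in the supported
  environment); an `analysis_config()` object is the in-R interface.
* Permutation p-values always use the +1 correction and are therefore
  valid (never zero, super-uniform under the null).
* BH adjustment is taken from `stats::p.adjust`.
* `assume_log2 = TRUE` throughout; readers apply log2(x+1) only on
  request, so RMA-style input is never double-transformed.

## Known limitations

* The exhaustive solver refuses components with more than 15 non-measured
  nodes; the branch-and-bound handles the pipeline's decomposed networks
  easily but is not engineered for dense thousand-node priors — wall-clock
  parity with industrial MILP formulations is a non-goal.
* xCell-style spillover correction, fgsea's multilevel p-values, VIPER's
  pleiotropy correction and NicheNet's prior construction are all reduced
  to their consumed essentials, as documented above.
* Printed values from the motivating study (e.g. specific NES values or
  interaction counts) depend on its cohorts and versioned resources and
  are not reproduction targets; the package's correctness claims are the
  oracle-equivalence, calibration and planted-recovery properties in
  `tests/testthat/test-acceptance.R`.
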