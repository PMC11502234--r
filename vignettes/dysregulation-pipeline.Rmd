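---
title: "From counts to networks: the dysnet analysis pipeline"
author: "dysnet authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From counts to networks: the dysnet analysis pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dysnet)
library(SummarizedExperiment)
```

# Scope

`dysnet` implements a complete bulk RNA-seq dysregulation analysis and its
network-biology sequels: a differential-expression chain built around
per-gene ANCOVA, weighted gene-coexpression module discovery with a
membership-permutation null and a driver-deletion weight-shift test,
protein-interaction network (PIN) topology analysis around maximal clique
centrality (MCC), and prepulse-inhibition (%PPI) metrics for acoustic
startle sessions. Every stage can be exercised end to end on seeded
synthetic data with a ground-truth record, which is how the package tests
itself.

# The differential-expression chain

The chain mirrors a bespoke but fully classical workflow:

1. **CPM with a log2 pedestal** — `cpmLogPedestal()` computes
   `log2(1e6 * count / libsize + 2)`. The pedestal of 2 keeps zeros finite
   (the attainable minimum is `log2(2) = 1`) and compresses shot noise at
   low counts. The later noise floor of 2.25 only makes sense on this
   scale — with a `log2(cpm + 2)` transform the floor sits just above the
   zero-count value, which is why the pedestal is applied inside the log.
2. **Cyclic loess** — `cyclicLowess()` equalizes location and spread across
   samples by loess-smoothing M against A for every sample pair (via
   limma's pairwise cyclic loess). Defaults: `span = 0.3`, 3 iterations;
   both exposed because smoother settings are a judgment call and published
   workflows rarely state them.
3. **Outlier flagging** — `flagOutlierSamples()` replaces a visual
   covariance-PCA inspection with a reproducible rule: a sample is flagged
   when its distance from the centroid in the PC1–PC2 plane exceeds
   `sdMultiplier` (default 3) robust standard deviations. Distances are
   themselves deviations from the centroid, so the robust SD is the
   normal-consistency-scaled median absolute distance about zero; a
   median-centered MAD over-flags badly here, because with a dozen samples
   the leading PCs are fit to the very extremes they are meant to judge.
   Under the i.i.d. simulation this rule flags nothing in >95% of runs and
   still catches a sample whose gene values have been scrambled.
4. **Batch correction** — `correctBatch()` removes additive batch terms per
   gene with a trait-preserving design (limma's `removeBatchEffect`).
   Perfect trait–batch confounding is refused with an error naming the
   aliased factors. Correcting already-corrected data is an identity to
   1e-8, which the tests assert.
5. **Noise-floor filtering** — `floorFilter()` removes genes with no sample
   above the floor (default 2.25, a value normally read off a fitted noise
   model; the derivation of the value itself is out of scope) and raises
   surviving sub-floor values to the floor. Idempotent by construction.
6. **ANCOVA** — `ancovaDEG()` fits `expression ~ trait + batch + sex` per
   gene by ordinary least squares and tests the trait term with a partial
   t-test. This is deliberately classical ANCOVA rather than moderated
   statistics: the method under study adjusts for covariates but does not
   borrow strength across genes. `log2FC` is the covariate-adjusted
   test-minus-reference difference; a gene is called when p passes the cut
   (0.05 strict, 0.1 relaxed) **and** `linearFC ≥ 1.25` or `≤ 0.8` — "at
   least 1.25-fold in either direction". Whether the p-values should be
   multiplicity-adjusted before thresholding is ambiguous in workflows of
   this kind, so `pAdjust = c("none", "BH")` is a switch, defaulting to
   raw ANCOVA p-values.

`runDEGChain()` wires these together, re-normalizing after outlier removal.

Under the null simulation (2,000 genes, 6 vs 6, two batches, balanced sex)
the fraction of genes at p < 0.05 sits in [0.03, 0.07], and planted
2-fold changes at NB dispersion 0.1 are called with ≥80% power — both
recomputed by `scripts/acceptance.R`.

# Coexpression modules

`buildTOM()` constructs the soft-thresholded adjacency (`|r|^β` unsigned by
default; a signed variant is available — the unsigned default reflects the
most common practice, not a documented choice of the original analysis) and
the topological overlap matrix (TOM). `pickSoftPower()` scans β = 1..20 for
the smallest power whose scale-free fit R² reaches 0.8; when no power
qualifies (e.g. structureless data) it falls back to the power where the R²
curve flattens — defined as the point from which every later change is
below 0.01, since a single small first difference can occur while the curve
is still rising.

## Module detection

The reference tree-cutting code for WGCNA-style dendrograms is not a
dependency here; `detectModules()` implements its own branch cut with the
same tunables:

* average-linkage clustering on `1 − TOM`, cut at 99% of the top merge
  height into branches;
* **recursive deep split**: a branch's two sub-branches become separate
  clusters when both hold `minSize` genes and their eigengenes are
  dissimilar (`1 − cor ≥ mergeCutHeight`); undersized sub-branches are shed.
  This separates trait-up from trait-down modules, which an unsigned metric
  glues together (their latent factors correlate through the trait), and
  fragments structureless branches — noise clusters have no shared factor,
  so their halves never agree and the recursion grinds them below
  `minSize`;
* a **cohesion filter**: a cluster is kept only if its mean internal TOM is
  at least 1.5× the network-wide mean, which blocks the occasional large
  but unstructured cluster from surviving as a module;
* **kME adoption**: background genes whose correlation with a module
  eigengene reaches `1 − mergeCutHeight` are adopted as module periphery
  (recovering genes shed during splitting);
* eigengene-correlation merging at `mergeCutHeight = 0.25`, and size-ranked
  labels `M1, M2, ...`.

Defaults `minSize = 30` and `mergeCutHeight = 0.25` follow common practice.
Eigengenes are the first principal component of the standardized module
expression, unit norm, oriented so the mean correlation with member genes
is nonnegative.

## Module–trait statistics, permutation null, drivers

`moduleTraitStats()` correlates eigengenes with 0/1-encoded covariates
(reference level → 0) and converts r to a two-sided p by the exact
t-transform with n − 2 degrees of freedom. `geneModuleStats()` reports MM
(gene–eigengene correlation) and GS (gene–trait correlation, signed by
default), plus the per-module GS~MM correlation computed on absolute
values. `selectDrivers()` takes each module's 95th MM percentile, ties
included. `permuteModuleValidation()` permutes gene→module labels
(preserving sizes) 40 times, recomputes eigengenes and trait correlations,
and flags a module as validated when its observed |r| exceeds every
permuted value — an envelope criterion rather than a p-value, which is the
natural reading of "no permuted module was equivalent" at 40 permutations.

`driverDeletionShift()` recomputes the module's TOM from its adjacency
block before and after deleting the driver rows/columns and compares the
two weight distributions by a two-sample Kolmogorov–Smirnov test. The
recomputation matters: drivers are high-connectivity genes, so their loss
depresses the topological overlap of every remaining pair, producing the
leftward shift the test looks for. (If one instead merely subsets the
intact weight list, D is bounded above by roughly twice the deleted
fraction — about 0.095 for 5% drivers — and the test cannot respond no
matter how central the drivers are. Raw-adjacency weights remain available
via `weights = "adjacency"` for exactly that subsetting comparison.)

# PIN topology

`loadInteractions()` parses STRING-dialect edge lists and recomputes the
combined score from the *selected* channels only (default: experiments,
databases, fusion) with the standard prior-corrected product rule
(p₀ = 0.041), so evidence from excluded channels cannot carry an edge over
the 0.9 threshold. Edges below threshold and the nodes they strand are
dropped.

`mccScores()` ranks hubs by maximal clique centrality,
`MCC(v) = Σ_C (|C| − 1)!` over maximal cliques through `v`; when no two
neighbors of `v` are adjacent every such clique is an edge and the score
reduces to the degree. Cliques are enumerated exactly (igraph's pivoting
Bron–Kerbosch) behind a configurable guard (default 10⁶ cliques) because
the worst case is exponential — high-confidence PINs are sparse and stay
far from it. The test suite checks MCC against a brute-force
subset-enumeration oracle on ~100 random graphs.

`topologicalCoefficients()` uses the NetworkAnalyzer-style convention:
`TC(v) = mean_u J(v,u) / k(v)` over nodes `u` sharing at least one
neighbor with `v`, where `J` counts shared neighbors plus one if `u` and
`v` are adjacent. The convention is stated because several inequivalent
definitions circulate; here any node with a qualifying partner gets a
value, and isolated or partnerless nodes score 0. In hub-and-spoke
networks TC falls as degree rises, which the tests assert on
preferential-attachment graphs.

`deleteNodesStats()` removes nodes, then prunes nodes the removal left
edgeless, and reports node/edge/component/mean-degree statistics before and
after — the fragmentation readout used to show hub dependence.
`growSeededNetwork()` grows a network from seed genes by direct
interactions only: candidates enter only through an edge to the current
network, to a fixpoint, so candidate-only chains stay out.
`hypergeomEnrichment()` is a generic overrepresentation engine over
user-supplied gene sets (upper-tail hypergeometric p, odds ratio with
Haldane correction, BH adjustment); it replaces proprietary annotation
services, whose contents are out of scope.

# Startle metrics

`percentPPI()` computes baseline startle as the mean over startle-alone
trials and reports, per prepulse trial type,
`%PPI = (1 − mean/baseline) × 100`, floored at 0%. A ratio of nonnegative
amplitudes can never be negative, so a literal "(ratio × 100), negative
values set to 0" rule would make the cap meaningless; the inhibition form
is the reading under which the cap does what it says. The raw response
ratio is emitted alongside as a diagnostic, and `sensitizationTrials()`
counts trial types whose normalized startle exceeds 100%.

# The synthetic-data generators

`simulateBulkCounts()` draws negative-binomial counts around log-normal
gene baselines scaled by log-normal library sizes, in a balanced design of
6 samples per genotype (3 of each sex) split across two sequencing batches
— the design of the experiment this emulates. Planted differential
expression shifts group means by `2^deLog2FC`; planted modules share a
latent factor `ρ·trait_z + sqrt(1 − ρ²)·ε` with ε orthonormalized against
the trait, so the factor's sample trait correlation is exactly ρ and the
expected module–trait correlation is analytic. Batches add gene-wise
N(0, 0.2) log2 offsets — enough to exercise the correction stage without
dominating the signal.

Defaults the source experiment does not pin down were chosen once as
typical of a filtered bulk matrix and exposed in `simConfig()`: baseline
mean counts log-normal around 100 (log2 sd 1.5), NB dispersion 0.1,
library sizes log-normal around 5×10⁵ for a 2,000-gene universe (CPM
normalization makes the absolute depth immaterial; read depth in the real
experiment was ~33M reads over a full transcriptome).

The canonical module-recovery conditions used by the tests and the
acceptance script are: 2,000 genes; a trait-up module (150 genes,
ρ = +0.9), a trait-down module (150 genes, ρ = −0.75), and a dominant
trait-independent background module (600 genes, ρ = 0), all with loadings
uniform in [0.5, 1.5]. The background module is deliberately the largest:
in real transcriptomes the leading coexpression axes (cell composition,
technical state) are usually not the trait-linked ones, and the
membership-permutation null relies on that — a permuted pseudo-module's
eigengene locks onto the dominant variance axis, which should *not* be the
trait. Without a dominant trait-independent axis, permuted mixtures
correlate with the trait almost as strongly as the planted modules and the
envelope criterion loses its meaning; worse, at 12 samples a random
eigengene's trait correlation has standard deviation ≈ 0.30, so the
maximum over 40 permutations routinely tops 0.75 unless permuted
eigengenes are anchored elsewhere. Module-recovery accuracy is scored as
the adjusted Rand index over the planted trait-module genes (the
background module's own recovery — degraded by the compositional coupling
that CPM induces between a dominant module and everything else — is
reported separately).

What the generators do **not** emulate: read-level artifacts (alignment,
duplication, GC bias), isoform structure, correlated gene-gene noise
beyond the planted factors, outlying RNA-quality failures (tests plant
outliers by scrambling a sample instead), and any real interactome
topology beyond preferential attachment plus planted cliques. Passing
recovery tests therefore demonstrates the machinery is correct and
calibrated under its assumed generative model, not that real tissue data
meet those assumptions.

`simulateInteractome()` plants a clique among the lowest-degree nodes of a
preferential-attachment backbone and decorates edges with STRING-style
channel scores. A planted K₅'s members carry MCC ≥ 4! = 24 and typically
occupy the top ranks, though a 500-node preferential-attachment tree's
degree tail reaches 24 in a minority of seeds, so domination is typical
rather than guaranteed. `simulateGeneSets()` and
`simulateStartleSession()` provide the matching fixtures for enrichment
and %PPI.

# Numerical notes and problem sizes

* All generators take explicit integer seeds; identical seeds give
  bit-identical output.
* The ANCOVA fit is a single QR decomposition shared across genes;
  constant genes get p = 1 rather than NaN.
* TOM computation is two dense matrix products; entries are clipped to
  [0, 1] and symmetrized against floating-point drift.
* KS tests on TOM weights ignore tie warnings (weights are effectively
  continuous).
* Test and acceptance problem sizes — 2,000 genes, 12 samples, 20
  replicate seeds, 500-node interactomes, 100 oracle graphs at n ≤ 15 —
  were chosen so the full suite completes in minutes on a single core
  while leaving the asserted margins comfortably away from their
  thresholds.

# Worked example

```{r example, eval = FALSE}
sim <- simulateBulkCounts(simConfig(nGenes = 2000, deFraction = 0.1,
                                    deLog2FC = 1, seed = 8))
res <- runDEGChain(sim$counts)
table(called = res$deg$called05)
mean(sim$truth$de_genes$gene %in% rownames(res$deg)[res$deg$called05])
```

# Known limitations

* Module detection is a bespoke branch-cut; it matches the intent of
  dynamic tree cutting but not any reference implementation line for line.
* The compositional coupling that CPM induces between a dominant module
  and the remaining genes is left in the data on purpose (it is real), and
  it caps recovery of very large modules.
* The permutation envelope is a 40-draw extremum; its false-positive
  behavior is a rank property (uniform under exchangeability, which the
  tests verify) rather than a calibrated p-value.
* `hypergeomEnrichment()` assumes the query is drawn from the stated
  universe; supplying a mismatched universe silently changes the null.
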