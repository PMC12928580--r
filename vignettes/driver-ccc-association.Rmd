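---
title: "Linking cancer driver genes to cell-cell communication signatures"
author: "cccmine"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking cancer driver genes to cell-cell communication signatures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cccmine)
```

## The problem and the model

Tumor progression is shaped both by cancer cell-intrinsic events (driver
gene mutations and copy-number changes) and by extrinsic cell-cell
communication (CCC) in the tumor microenvironment — ligand-receptor
signaling between cancer cells, macrophages, T cells and other
compartments. `cccmine` asks, in the style of an association study,
which recurring communication structures travel together with which
driver genes across a patient cohort.

The units of the analysis are:

* **Intrinsic factor** — a per-patient binary indicator of a driver-gene
  event (mutation or CNV call), one column per driver.
* **Extrinsic factor** — a frequent subnetwork of the per-sample
  *multi-cell-type communication (MCTC) network*: an undirected labeled
  graph whose nodes are (gene, cell type) pairs and whose edges are
  intracellular gene interactions or intercellular ligand-receptor
  contacts. Frequent subnetworks are connected subgraphs occurring in at
  least `minSupport` samples.
* **Association** — for each driver *In* and each frequent subnetwork
  *Ex*, a one-sided Fisher's exact test on the 2x2 co-occurrence table
  over samples, alternative "greater" on the co-occurrence cell, because
  the question is which communication structures *emerge together with*
  a driver rather than mutually exclude it. P-values are
  Benjamini-Hochberg adjusted; subnetworks with adjusted p below 0.05
  are called **CCC signatures** of that driver and ranked by descending
  significance.
* **IE pathway** — the mechanistic bridge: the MCTC network is expanded
  with intracellular first-order neighbors, round by round, until the
  driver gene enters the cancer-cell compartment, and the shortest paths
  from the driver node to the signature's nodes are reported.

## Pipeline stages and the choices behind them

### Preprocessing

Counts are normalized per cell to 10,000 total counts and
`log1p`-transformed (`logNormalizeCounts()`), the standard library-size
recipe for single-cell data; pre-normalized matrices are accepted
directly. An optional protein-coding whitelist restricts the gene
space. Gene symbols are matched case-sensitively after whitespace
stripping — deterministic behavior without external alias databases.

The low-expression rule ("expressed in at least 5% of the cells of a
given type") is implemented as a per-(gene, cell type) retention *mask*
(`filterLowExpressed()`), not as global gene dropping, so macrophages
and cancer cells may legitimately keep different gene sets. The filter
is applied once on the full cohort, before resampling: the bootstrap
draws below only reweight cells within a patient, so fractions computed
on the full compartment are the stabler estimate.

### Pseudo-samples

Single-cell cohorts are small, so patients are up-sampled into bootstrap
pseudo-samples (`generatePseudosamples()`): a patient is *eligible* when
it has at least `minCells = 20` cells in every focal cell type; each
eligible patient yields `repeats = 5` pseudo-samples, each drawing
`round(0.5 * n_t)` cells per focal type *t* with replacement
(round-half-to-even, the deterministic default of numeric libraries).
Undersized patients can either be dropped or included once, unsampled,
with replicate index 0 — both policies occur in practice, so it is a
flag. The count identity `|eligible| * repeats + |included undersized|`
is tested as a property over random cohorts.

Randomness is keyed per (patient, replicate) by hashing the patient
identifier into a 31-bit stream seed: adding or removing a patient
never perturbs another patient's draws, which makes incremental cohort
growth reproducible.

Non-focal cell types are passed through unresampled; they only serve as
background context for network backends that want them.

### MCTC networks

Per-cell-type-pair signal-transduction networks come from a pluggable
backend: either externally computed edge lists (`readNetwork()`, which
discards any node prizes and edge weights — mining is structural), or
the built-in `litePairwiseNetwork()`, which adds a ligand-receptor edge
when the ligand is expressed in at least `exprFracThreshold` of the
sender type's cells and the receptor likewise in the receiver type
(default 0.1, the conventional "expressed" cutoff in CCC screening),
plus intracellular interaction edges within one hop of the
ligands/receptors in use. The pairwise networks are unioned
(`unionNetworks()`, set semantics) into one MCTC network per
pseudo-sample. Edges are undirected for mining; ligand-to-receptor
directionality is a display property, not an isomorphism label.

### Frequent subnetwork mining

`gspanMine()` enumerates exactly the connected, label-preserving
isomorphism-distinct subgraphs with at most `maxEdges` edges occurring
in at least `minSupport` networks. Patterns are grown edge-by-edge
through their embeddings and de-duplicated by canonical minimum DFS
code; since a graph supports a child pattern exactly when one of its
parent embeddings extends there, support sets are exact. Containment is
standard subgraph isomorphism on node labels `gene@celltype` and the
intracellular/intercellular edge kind; occurrences need not be induced.
Output order is canonical-code order, independent of input order.

Defaults: `maxEdges = 5` (reported signatures are one or two
interactions; the cap bounds the exponential search), single-node
patterns excluded (signatures are interactions), and support counted
over pseudo-samples — the unit the occurrence matrix is defined on. An
optional patient-level support mode is deliberately *not* provided as a
default because five correlated replicates per patient inflate support
for every pattern equally; `chooseSupport()` instead suggests a
threshold from the expected driver prevalence
(`ceiling(prevalence * n)`).

The miner is verified against an independent brute-force oracle that
enumerates every connected edge subset of every graph and
canonicalizes by a method that shares nothing with DFS codes
(node labels are unique within an MCTC network, so sorted labeled edge
sets are a complete isomorphism invariant).

### Association testing

`associateAll()` skips drivers present in no or in all samples (a
driver carried by everyone cannot discriminate anything and is dropped
with a warning). The BH family is per driver: all mined patterns tested
against one driver form one family, matching the per-driver signature
counts such analyses report; a pooled global family is available behind
a flag. Significance ties in the ranking are broken by higher odds
ratio, then larger co-occurrence count, then pattern id — the ordering
must be deterministic for reproducible output. The odds ratio is the
plain sample `ad/bc` (infinite when `bc = 0` with co-occurrence
present), kept separate from the p-value, which is the exact
hypergeometric upper tail.

Pseudo-samples from one patient are statistically dependent; the
default treats them as the analysis unit (they are what the occurrence
matrix is defined on), and the conservative alternative — testing at
patient level — can be had by mining with one pseudo-sample per
patient.

### IE pathways

`expandToDriver()` grows the network in breadth-first rounds within the
driver's own cell type (a driver is cancer-cell-intrinsic; expansion in
all types is a flag) and stops at the first round that contains the
driver — the stopping round is provably minimal, tested against a
BFS-ball oracle. `maxRounds = 6` guards non-termination, with explicit
unreachability flagging rather than failure. `iePaths()` returns
shortest paths per signature node (`all_shortest` keeps every
co-minimal route; `one` picks the lexicographically smallest), and
`signatureDistance()` summarizes the minimum over signature nodes.
Unions of paths export to SIF/GraphML/TSV for Cytoscape-style
visualization; functional enrichment of the exported gene lists is left
to dedicated tools.

### Downstream evaluators

* `mhc1Score()` — arithmetic mean of the nine-gene MHC-I core set
  (HLA-A/B/C, TAP1/2, NLRC5, PSMB8/9, B2M).
* `cytScore()` — geometric mean of GZMA and PRF1 with a pseudocount of
  0.01, the convention of the original cytolytic-activity literature
  (the pseudocount only matters at zero expression and is exposed).
* Survival: `subtypeSplit()` dichotomizes a cell type at the median
  expression of a signature gene (ties at the median go to Lo —
  deterministic and documented), `nnlsDeconvolve()` or an external
  abundance table estimates the Hi-subtype abundance per bulk sample,
  `stratifyBulk()` forms the 2^k combinatorial Hi/Lo groups over the
  signature's genes (abundance medians are computed within the analyzed
  subcohort), and `logrankGroups()` runs the k-group log-rank test.
* `ksDriverCall()` — per-patient, per-candidate-gene two-sided
  two-sample Kolmogorov-Smirnov test of tumor-cell versus
  reference-diploid CNV value distributions, BH-adjusted within each
  patient (a per-cohort family is a flag), called at adjusted p < 0.01.
  CNV inference itself is consumed as input, not performed.

## What the synthetic cohorts emulate

`simConfig()` fixes the simulated study conditions. The network-level
generator (`simulateNetworkCohort()`) is the primary test path: driver
status is Bernoulli(0.4) over 60 samples, three planted motifs appear
with probability 0.9 given the driver and 0.1 otherwise (an odds ratio
of 81), three null motifs appear independently of the driver, and a few
random background edges are drawn per sample from a disjoint label
space. The expression-level generator (`simulateExpressionCohort()`)
is the integration path: 12 patients, three cell types, 60 cells per
type, negative-binomial counts with baseline mean 0.3 and size 1
(sparse, overdispersed, a caricature of droplet data), with motif
ligands/receptors shifted to mean 3 in their designated cell types so
the expression-threshold backend recovers the planted edges.

These generators deliberately do **not** mimic ambient RNA, doublets,
batch effects, cell-type misassignment or realistic gene-gene
correlation. Passing tests therefore demonstrate that the machinery —
resampling accounting, mining exactness, test calibration, power at a
known effect size, path minimality — is correct, not that any
particular biological dataset will yield signal.

## Numerical and degenerate-input choices

* Fisher p-values use the exact hypergeometric tail; no asymptotics.
* An all-ones or all-zeros pattern column yields p = 1 by construction
  (no discrimination), not an error.
* All-zero cells are left all-zero by normalization, with a warning.
* A median split over identically expressed cells is refused with
  guidance rather than silently producing an empty arm.
* NNLS coefficients are normalized to sum to one; an all-zero fit is
  warned about and left unnormalized. Rank-deficient signature matrices
  are an error.
* KS tests on tied CNV values fall back to the approximate p (the
  tie warning is suppressed, as ties are ubiquitous in windowed CNV
  output).

## Problem sizes used by the checks

The shipped verification suite mines one hundred random cohorts of up
to eight-node/ten-edge graphs against exhaustive enumeration, runs 200
null-cohort replicates for type-I calibration and 100 replicates at
the planted effect for power, 100 random expansions for path
minimality, and exhausts all Fisher tables up to n = 12 against direct
tail enumeration. These sizes keep the complete run in the
low-minutes range on one core while leaving the checked claims exact.

## Known limitations

* The lite network backend is an expression-threshold heuristic; it
  stands behind the same interface as externally computed
  signal-transduction networks but does not approximate their
  information-theoretic edge selection.
* Dependence between pseudo-samples of one patient is not modeled in
  the test; per-driver BH controls the FDR over patterns, not over
  patients.
* Continuous intrinsic factors (e.g. copy-number dosage) are out of
  scope; the association is binary-binary by design.
* Mining cost grows quickly with `maxEdges` and with repeated labels
  across samples; the support threshold is the practical handle, and
  `chooseSupport()` makes the trade-off explicit.

## A minimal run

```{r pipeline}
cfg <- simConfig(nSamples = 60, seed = 1)
sim <- simulateNetworkCohort(cfg)
patterns <- gspanMine(sim$networks, minSupport = 12, maxEdges = 2)
F <- encodeOccurrence(patterns, sim$networks)
res <- associateAll(F, sim$drivers, patterns = patterns)
head(res[order(res$p_adj), c("pattern_id", "a", "b", "c", "d",
                             "p_adj", "rank", "signature")])
```

The three planted motifs surface as the top-ranked signatures; the
null motifs do not.
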