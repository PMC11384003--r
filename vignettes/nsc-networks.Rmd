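---
title: "Mapping neurosecretory-cell networks: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping neurosecretory-cell networks: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nscnet)
```

## The problem

Neurosecretory cells (NSC) of the insect brain — in the pars
intercerebralis, pars lateralis, and subesophageal zone — release peptide
hormones such as insulin-like peptides, DH44, DH31, corazonin, ITP, CAPA and
hugin into circulation, and together form the functional analogue of the
hypothalamus–pituitary axis. Two kinds of data now make their connectivity
tractable at single-cell resolution: whole-brain synapse-level connectomes
with neuron annotations, and single-cell transcriptomes of brain and
peripheral tissues. `nscnet` implements the computations that link the two:
it builds thresholded synaptic graphs, classifies NSC by their presynaptic
input profiles, traces sensory-to-endocrine pathways, summarises shared and
strong inputs and synaptic outputs, and infers putative paracrine
ligand–receptor networks from co-expression.

All results of these analyses are *putative* connectivity: synapse counts
come from automated synapse prediction on electron microscopy, and paracrine
edges are expression-based predictions, not demonstrations of signalling.

## Synaptic graph model and thresholds

A connectome here is a directed multigraph collapsed to unique neuron pairs:
duplicate `(pre, post)` rows are summed at load time, so downstream code
only ever sees one weighted edge per ordered pair. Neuron ids are kept as
opaque strings throughout — connectome root ids exceed the 53-bit integer
range of doubles, and numeric coercion would silently corrupt them.

Connectivity analyses stand or fall with the definition of a "connection".
`threshold_config()` centralises it:

* `significance = 5` synapses — the default for a significant connection.
  The threshold is applied **inclusively** (`count >= 5`) everywhere. The
  inclusive convention is a package decision: descriptions of this
  threshold in the literature oscillate between "a threshold of 5" and
  "more than five", and a single uniform rule keeps every report
  monotone in the threshold (the row set at threshold *t1* is always a
  superset of the row set at *t2 ≥ t1*, a property the test suite checks
  for every report).
* `output_relaxed = 2` — NSC make few output synapses, so output analyses
  can be re-run at this relaxed threshold; relaxed reports are supersets of
  the strict ones.
* `strong = 50` — "strong" input connections, again inclusive.
* `nt_cutoff = 0.62` — transmitter prediction scores for the fast-acting
  transmitters (acetylcholine, glutamate, GABA) are only trusted when the
  winning score is **strictly greater** than 0.62; anything else, including
  an exact tie between two transmitters, is `unknown`. The transmitter of a
  hop in a pathway is a property of its presynaptic neuron, not of
  individual synapses.
* `max_hops = 3` — a "hop" is one directed significant edge, so the default
  3-hop olfactory pathway ORN → projection neuron → interneuron → NSC
  visits four neurons.

Self-loop edges are dropped with a warning (they carry no meaning at this
resolution), and dangling edge endpoints are either an error (strict mode)
or auto-created as `unknown`-class neurons so that lenient loading of
partial exports still yields a valid graph.

## Input-profile clustering

NSC subtypes are recovered from connectivity alone by clustering the
NSC × presynaptic-partner synapse-count matrix. The similarity is the
cosine

$$S_{ij} = \frac{\langle x_i, x_j\rangle}{\lVert x_i\rVert\,\lVert x_j\rVert},$$

computed on **raw synapse counts**: cosine similarity is invariant to
per-row scale, so no row normalisation is needed, and counts retain the
relative weighting of strong partners. For non-negative counts
$S_{ij} \in [0,1]$ with unit diagonal; both properties are enforced to
within $10^{-12}$ in tests. NSC with no significant input at all (most
ITP-expressing lateral NSC in adult data) cannot be placed in this space;
they are moved to an explicit `excluded` list rather than silently dropped,
because a silent drop would bias subtype counts.

Clustering is agglomerative on the distance $1 - S$ with **average
linkage** as the default. The linkage is genuinely an open choice — the
similarity structure is blocky enough that single, complete and average
linkage agree on clean data — and average linkage is the conventional
compromise for similarity-derived distances; it is exposed as a parameter.
The number of clusters is a user parameter (`k`), since no cut criterion is
canonical for this kind of data; rows are sorted lexicographically by id
before agglomeration so the merge order, and hence the labels, are
deterministic for a given matrix. Cluster-to-subtype naming uses anchor
cells of known identity when available, falling back on matching cluster
sizes against the reference catalog (`nsc_subtype_catalog()`), which is how
an 18-cell medial cluster is recognised as the insulin-producing m-NSC.

Morphological heterogeneity within subtypes is summarised by PCA of four
per-cell features (cable length, surface area, cell size, nuclei volume).
Units of the four features differ by construction, so columns are z-scored
before the decomposition; zero-variance columns are dropped with a warning
rather than producing NaNs. The explained-variance fractions equal the
eigenvalue fractions of the feature correlation matrix, which the tests
verify against an independent eigen-decomposition.

## Pathway tracing

`khop_shortest_pathways()` enumerates, for every source–target pair, **all**
simple directed paths of the minimum hop length through the
significant-edge graph, provided that minimum is at most `max_hops`. Ties
are kept deliberately: parallel relays of equal length (e.g. several
projection neurons linking the antennal lobe to one NSC) are biologically
meaningful and are all reported. Hops are unweighted — path length is the
edge count, not a synapse-count sum; synapse counts annotate the hops
afterwards. `max_hops > 6` is refused by default: in a brain-scale graph
almost every neuron reaches every other within about four hops, so deeper
searches produce combinatorial output with no interpretable structure (the
guard is overridable). The search itself delegates to igraph's
shortest-path machinery; the package's tests compare the full result sets
against an exhaustive depth-first enumeration oracle on hundreds of random
graphs, so the delegation is verified, not trusted.

Disynaptic tracing defines *sensory interneurons* operationally: a neuron
presynaptic to an NSC is a sensory interneuron when it lies on a
sensory → interneuron → NSC chain whose two hops **each** pass the
significance threshold; neurons presynaptic to NSC without significant
sensory input are non-sensory interneurons. Shared-input analysis counts,
for each presynaptic neuron, the number of distinct NSC *subtypes* it
significantly contacts (contacting several cells of one subtype counts
once), and reports the histogram over that number together with the
multi-target neurons themselves.

## Paracrine network inference

Expression handling follows standard single-cell practice: raw counts are
normalised per cell to a fixed library size (default 10,000) and
log(1 + x)-transformed. Cell-type gating predicates (conjunctions such as
`Crz > 3 & sNPF > 3 & Dh44 == 0`) evaluate on this normalised layer with
strict comparisons — the thresholds used for NSC identification are
log-scale magnitudes. A cell *expresses* a gene when its **raw** count is
positive; percent-expressing is therefore independent of normalisation.

The expression score of a gene in a cluster is

$$\mathrm{score} = \mathrm{scaled\ expression} \times \mathrm{pct\ expressing},$$

on a 0–100 scale. "Scaled expression" is not canonical across single-cell
toolkits, so the package makes its definition explicit and pluggable: the
default is per-gene **min–max scaling of cluster-mean normalised
expression** to [0, 100] across the clusters being compared (the
highest-expressing cluster maps to 100, the lowest to 0; an all-zero gene
maps to 0 everywhere and a degenerate range to 100), with a z-score variant
available. This explicitness matters because the ligand score filter of 2.5
only has meaning relative to the scaling.

Presence rules are conservative and inclusive at their boundaries: a
neuropeptide is *present* in a cluster when at least 50% of its cells
express it **and** its score is at least 2.5; a receptor is present when at
least 5% of cells express it. The asymmetry (50% vs 5%) reflects that false
ligand calls propagate into many false edges, while receptors are routinely
expressed at low, hard-to-capture levels. For hormones with two receptors,
only the higher-scoring present receptor in a target cluster is used; exact
ties break to the lexicographically smaller gene name for determinism. The
three co-produced insulin-like peptides (Ilp2, Ilp3, Ilp5) act through one
receptor and are treated as a single ligand by **per-cell averaging before
any scoring** — the stricter reading of "average expression", under which
the group's percent-expressing is the fraction of cells whose mean is
positive. A paracrine edge's weight is
$\mathrm{score}_\mathrm{ligand} \times \mathrm{score}_\mathrm{receptor} / 100
\in (0, 100]$; zero-weight edges are never emitted, and a hormone whose
receptors are absent from every cluster contributes no edges at all (as
happens for CAPA and ITP in adult brain transcriptomes).

## What the synthetic generators emulate

`generate_connectome()` realises the structural motifs the analyses are
designed to detect, with ground truth recorded for scoring:

* **Block-structured NSC inputs.** Each planted subtype has a private pool
  of presynaptic neurons (default 12); each pool neuron contacts each NSC
  of its subtype with probability 0.9. Cross-block noise wires a foreign
  pool neuron onto an NSC with probability `noise_rate × 0.9` and a weaker
  count distribution, so `noise_rate` interpolates between perfectly
  separable blocks (0) and near-exchangeable inputs (1).
* **Layered sensory chains.** Planted ORN → PN → interneuron → NSC chains
  with node-disjoint relays, so at zero noise the shortest 3-hop pathway
  set equals the planted chain list exactly.
* **Over-dispersed synapse counts.** Counts are negative binomial, shifted
  by the significance threshold so planted edges are significant by
  construction; this mimics the heavy right tail of real synapse counts.
* Direct gustatory inputs and strong (≥ 50 synapse) NSC → descending
  outputs, to exercise the monosynaptic and output reports.

`generate_expression()` plants ligand–receptor pairs as genes expressed in
80% of the cells of one cluster at high magnitude and **nowhere else**,
over a background of genes sparsely expressed everywhere (2% of cells);
decoy pairs drawn from background genes probe the precision of edge
detection. Default sizes are deliberately desk-scale (4 subtypes × 6 NSC,
~130 neurons and ~300 edges; 6 clusters × 150 cells, 310 genes), so a full
pipeline run takes seconds.

What passing these tests does **not** show: the generators do not reproduce
the degree distribution, spatial statistics, annotation noise, or
proofreading artefacts of a real connectome, nor ambient RNA, doublets, or
batch structure in real transcriptomes. Recovery of planted structure is a
correctness check of the algorithms, not a claim about statistical power on
real data.

## Numerical and degenerate-input choices

* Cosine similarity clamps floating-point excursions above 1 and fixes the
  diagonal at exactly 1; an all-zero row reaching the computation is an
  internal error (exclusion must happen upstream).
* Min–max scaling clamps to [0, 100] (the ratio `100·a/a` can exceed 100 by
  ulps) and maps an all-zero gene to 0 without division errors.
* Empty cells normalise to all-zero profiles rather than NaN.
* Empty inputs (header-only tables, NSC sets with no significant partner)
  yield empty tables, never errors; genuinely invalid inputs (non-positive
  synapse counts, transmitter scores outside [0, 1], duplicate ids,
  unlabeled NSC in the shared-input analysis) fail fast with named errors.
* All tie-breaks are deterministic: lexicographic id order in clustering
  input, lexicographic receptor names, stable sort orders in every report.

## Validation strategy and problem sizes

The test suite checks each stage against an independent oracle: exhaustive
depth-first path enumeration on random graphs of up to 30 nodes and 120
edges (200+ graphs at mixed thresholds for the acceptance run), the
closed-form contingency formula for the adjusted Rand index, an
eigen-decomposition oracle for the PCA, and hand-computed fixtures for
every scoring rule and boundary (49/50 synapses, 0.62 score, 50%/5%/2.5%
presence). Recovery runs use 20 seeds per condition; these sizes make the
whole suite run in well under a minute while keeping every stochastic check
comfortably away from its decision boundary.

## Limitations

* The package analyses whatever annotation table it is given; it does not
  identify NSC in a raw connectome (that step is anatomical, not
  computational).
* Cluster count `k` and the ORN behavioural category table are user
  choices; defaults ship as fixtures, not as ground truth.
* Paracrine inference ignores transport, degradation, receptor affinity and
  spatial proximity — edge weights order hypotheses, they do not estimate
  signalling strength.
* Morphology features are taken as supplied; the package does not compute
  them from meshes or skeletons.
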