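---
title: "From copy-number alterations to network hubs: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From copy-number alterations to network hubs: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cnanet)
```

`cnanet` connects tumor copy-number alterations (CNAs) to protein–protein
interaction (PPI) network topology. This vignette is the package's own account
of the method: the model and its assumptions, the parameters that matter, what
the synthetic-data generator does and does not emulate, and the numerical and
design choices made where the procedure was genuinely open.

## The analysis model

The unit of observation is a *sample/condition pair*: one tumor sample from
one patient, taken either at diagnosis (`pre`) or after induction chemotherapy
(`post`). The analysis assumes:

* CNAs are reported as **segments** — intervals with a mean log2 tumor/reference
  intensity ratio and a supporting probe count. Segmentation itself (e.g.
  ADM-2 on probe intensities) happens upstream.
* Dosage effects act through the genes a region carries, so the **cytoband**
  is the unit of selection and the protein-coding genes overlapping altered
  cytobands are the candidate players. Gains and losses are pooled into a
  single gene set per sample/condition: both raise and lower dosage of
  regulators, and the method asks which genes are topologically central, not
  in which direction they move. (Per-direction sets are available via the
  `directions` argument of `build_gene_set()`.)
* Interactions are undirected, unweighted and evidence-scored per channel on
  the 0–1000 STRING scale. Filtering is done per channel *before* any network
  is built, so network topology never depends on the text-mining channels.
* Topological relevance is summarised by three centralities, and "relevant"
  means *strictly above the network mean* for all three — the
  hub–bottleneck–switch (HBS) conjunction.

## Calling gains and losses

`classify_cna()` implements the standard aCGH calling rule: gain if
`mean_log2 > 0.25`, loss if `mean_log2 < -0.25` (log2 ratio units), and
`filtered` whenever the probe count is 3 or fewer — "more than 3 probes" is
read strictly, so 4 probes is the minimum eligible support. All comparisons
are strict; a segment at exactly 0.25 is neutral. Classification is a pure
function of `(mean_log2, probe_count, thresholds)` and is idempotent. A
"call" is any segment classified gain or loss; `count_cna_calls()` tallies
them per sample/condition.

Coordinates are 0-based half-open internally; segment files use 1-based
inclusive coordinates (the vendor-report convention) and BED-like files are
0-based half-open. Conversion happens only at the read/write boundary.

**Overlap rule.** A segment supports a cytoband, and a gene belongs to a
region, when the intervals overlap by at least one base. Any-overlap is the
most inclusive choice and the easiest to audit; it errs toward including
boundary genes rather than silently dropping them.

**Recurrence.** `recurrent_cytobands()` keeps cytobands altered in at least
`min_samples` distinct samples per condition (default 2). Opposite directions
in different samples still count as recurrent and are flagged
`concordant = FALSE` rather than excluded — discordant recurrent bands are
biologically interesting, not noise. A stricter present-in-all-samples
criterion is the same function with `min_samples` equal to the number of
samples; both conventions appear in practice and neither is canonical, so the
choice is a parameter, not a constant.

## Network construction and centralities

`read_interactions()` keeps an edge when **at least one** selected evidence
channel reaches `min_score` (default 400 ≡ confidence 0.4). Requiring every
selected channel to pass simultaneously (`combine = "all"`) is also
implemented, but as a non-default: demanding co-expression *and* database
*and* experimental support at 0.4 each discards nearly every known
interaction, which is rarely what a score filter is meant to do.

`induce_ppi_network()` restricts to edges with both endpoints in the gene
set, drops self-loops, merges duplicate/reciprocal records, and keeps only
the largest connected component; a size tie is broken deterministically by
the component containing the lexicographically smallest symbol. Isolated
nodes are removed, so every downstream network is simple and connected.

`node_centralities()` fixes the conventions that the mean-threshold
classification depends on:

* **degree** — incident edge count;
* **betweenness** — Brandes' dependency accumulation on the unweighted graph:
  unnormalized, each unordered source–target pair counted once, endpoints
  excluded. Any normalization would rescale all scores *and* the mean
  identically for a fixed network, but mixing conventions across libraries
  changes reported values, so one is pinned here;
* **eigenvector** — the principal eigenvector of the adjacency matrix,
  max-normalized so the top node scores exactly 1. Max-normalization (rather
  than the 2-norm) makes scores comparable across networks of different size;
  classification is invariant to the choice since scaling preserves order and
  scales the mean identically.

**Numerical choices.** The power iteration runs on `A + I` rather than `A`:
on a connected graph the shift leaves the principal eigenvector unchanged
while making the matrix primitive, so the iteration also converges on
bipartite graphs, where iterating `A` itself oscillates between two
subsequences. Convergence is declared when successive max-normalized iterates
differ by less than `1e-10` in the infinity norm, with a hard cap of 1000
iterations and an explicit error (reporting the cap) on non-convergence. A
single-node network has eigenvector centrality 1 by convention; empty,
directed, non-simple or disconnected inputs are rejected with explicit
errors rather than silently repaired.

`classify_hbs()` compares each metric to its arithmetic mean over the
network's nodes, strictly. Strictness is deliberate: on a vertex-transitive
graph (a ring, a complete graph) every score equals the mean and no node is
labeled, which is both the honest reading of "above average" and a clean
testable case. The three thresholds are reported with the labels.

## Comparative reports and enrichment

`intersect_hbs()` and `cross_condition_overlap()` are plain set arithmetic
with reproducibility guarantees: member lists are always emitted sorted, and
reports are invariant under permutation of the inputs. Node identity is the
bare gene symbol; any protein-identifier aliasing must happen upstream.

`enrich_terms()` implements over-representation as the one-sided
hypergeometric upper tail,

$$p = \sum_{i=k}^{\min(n,K)} \frac{\binom{K}{i}\binom{N-K}{n-i}}{\binom{N}{n}},$$

which is identical to a one-sided Fisher's exact test on the 2×2 table; the
explicit form fixes the sidedness. Annotations are closed under the
true-path rule before testing (a gene annotated to a term is annotated to all
its ancestors), the universe defaults to every gene with at least one
propagated annotation (overridable), terms annotated to no universe gene are
never tested, and the BH family size is the number of tested terms.
Multiplicity is controlled by Benjamini–Hochberg; thresholding the adjusted
q-values at α selects exactly the hypotheses the BH step-up procedure rejects
at level α. No elim/weight-style decorrelation of the ontology hierarchy is
attempted — it would change p-values in ways that cannot be verified against
a closed form. `filter_generic_terms()` removes catch-all terms ("regulation
of biological processes", ...) by id or exact name after testing, preserving
order and reporting the removal count.

## The synthetic-data generator

`simulate_study()` emulates the four inputs of a three-patient paired study
with known ground truth. All generators are pure functions of
`(parameters, seed)`; the RNG is pinned (Mersenne–Twister, inversion normals,
rejection sampling) and recorded in `truth.json`, and outputs are byte-stable
across runs.

* **Genome** — chromosomes tiled by equal 1-Mb cytobands; 20-kb genes placed
  uniformly within bands; 10% labeled non-coding by default to exercise the
  coding filter.
* **CNA profiles** — planted cytobands receive segments with
  `mean_log2 ~ Normal(±0.5, 0.05)` and 5–40 probes. The effect size must
  exceed `gain_threshold + 3·noise_sd` (checked before anything is written),
  so planted calls survive thresholding by construction, not luck. A *core*
  of cytobands is gained in every sample and condition — a recurrent backbone
  in the spirit of the 17q gain of neuroblastoma — guaranteeing material for
  recurrence logic and a shared home for the planted regulators. Background
  bands get neutral segments, plus one high-amplitude decoy with ≤ 3 probes
  per profile that the probe filter must remove.
* **Interaction table** — sequential attachment over the coding genes.
  Planted regulators join first and attract new edges with weight
  `attachment_bias · (degree + 1)`; background nodes attach with uniform
  weight 1. The rich-get-richer dynamics therefore act only on the
  regulators: they form the heavy upper tail of the degree distribution
  (degrees an order of magnitude above the mean) while background degrees
  concentrate tightly below the mean. This margin is what makes the
  strict-mean HBS rule recover the planted set by construction — background
  nodes essentially cannot be hubs, and HBS ⊆ hubs. Channel scores keep
  baselines below 400, let text-mining roam the full scale (it must never
  rescue an edge), and push one random evidence channel above 400 with
  probability 0.9 per edge. A few reciprocal duplicate rows exercise edge
  merging.
* **Ontology** — a random tree of ≤ `dag_depth` levels; the root and its
  first child carry deliberately generic names that the default blocklist
  removes. The planted term is a **leaf** at depth ≥ 2: annotations propagate
  upward, so only a childless term keeps a small, specific annotation set
  after true-path closure — planting an internal term would dilute it into
  near-genericity. It annotates the planted gene set (the regulators plus
  random coding genes); every other non-root term annotates each gene
  independently at the background rate.

The small profile (2 chromosomes × 8 cytobands × 15 genes, 1200 edges,
5 regulators, 50 terms) runs the full pipeline in a few seconds and is the
size used throughout the test suite; the default profile is a ~1000-gene,
6000-edge version of the same design.

**What the generator does not emulate:** probe-level intensities and
segmentation artifacts, FFPE degradation, tumor heterogeneity and clonal
evolution, realistic gene/cytoband size variation, correlated annotation
structure, and the community structure of real interactomes. Passing the
planted-recovery tests therefore demonstrates that the pipeline's logic is
correct under its stated assumptions — not that real tumor data would yield
equally clean HBS sets. On real data the HBS conjunction typically labels
tens to hundreds of genes per network, not exactly the planted handful.

## Verification strategy

Every algorithmic component is checked against an independent oracle that
shares no code with the implementation: betweenness against a matrix-power
shortest-path-counting oracle (exhaustively on all ~1000 connected graphs
with ≤ 7 vertices via the graph atlas, plus 200 random 8–12-node graphs) and
against igraph; eigenvector centrality against a dense symmetric
eigendecomposition (tolerance 1e-8); hypergeometric tails against explicit
binomial-coefficient sums, exhaustively for every configuration with
`N ≤ 30` (where all terms are exact in double precision); BH against the
step-up formula written out directly. Planted-structure recovery is measured
across 20 seeds at the small profile's default parameters, and the whole
simulate-then-analyse round trip is checked for byte-identical outputs.

## Limitations

* Mean-threshold labeling is scale-free but crude: it has no notion of
  statistical significance, and HBS counts are not comparable across networks
  of very different size or density.
* The pipeline trusts the upstream segment calls; no re-segmentation or
  quality control is attempted.
* Identifier handling is by bare symbol; interaction files keyed by protein
  IDs need an upstream alias map.
* Overlap significance (whether k patients sharing m HBS is surprising) is
  out of scope; the reports are descriptive counts.
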