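# cnanet

Copy-number alterations (CNAs) are a dominant mutational mechanism in
neuroblastoma and many other solid tumors: whole chromosome arms and cytobands
are gained or lost, and the genes they carry change dosage together. A common
way to move from long, uninterpretable CNA gene lists to candidate
disease-driver genes is topological: build the protein–protein interaction
(PPI) subnetwork induced by the altered regions and rank its nodes by network
centrality. `cnanet` packages that analysis as a tested, reproducible,
tidyverse-style pipeline for paired pre-/post-chemotherapy tumor profiles:

1. **CNA calling** from segment-level aCGH reports: a segment is a *gain* when
   its mean log2 ratio exceeds 0.25, a *loss* below −0.25, and is discarded
   unless it is supported by more than 3 probes (all comparisons strict).
2. **Cytoband → gene mapping**: altered cytobands are selected (optionally
   only those recurrent across patients), and the protein-coding genes they
   overlap form one gene set per sample and condition.
3. **Network induction** from a multi-channel interaction table in the STRING
   protein-links-full layout: edges must reach a confidence score of 400 (on
   the 0–1000 scale) in at least one of the six evidence channels
   (co-expression, database, experiments, and their homology-transferred
   variants); self-loops and duplicate edges are removed and only the main
   connected component is kept.
4. **Hub–bottleneck–switch (HBS) classification.** For each node `v` of a
   network with node set `V`:
   - degree `deg(v)`;
   - betweenness `B(v) = Σ_{s<t, s,t≠v} σ_st(v) / σ_st`, where `σ_st` counts
     shortest paths (Brandes' algorithm; unnormalized, each unordered pair
     counted once, endpoints excluded);
   - eigenvector centrality `x` with `A x = λ_max x`, scaled so
     `max(x) = 1` (power iteration on the adjacency matrix).

   A node is a **hub** if `deg(v) > mean(deg)`, a **bottleneck** if
   `B(v) > mean(B)`, a **switch** if `x(v) > mean(x)`, and an **HBS** if all
   three hold at once. Strict inequalities mean a regular network yields no
   labels at all.
5. **Comparative reports**: per-sample HBS sizes, all pairwise and k-way
   common HBS within each condition, and the pre-vs-post overlap per sample
   and globally.
6. **Over-representation**: one-sided hypergeometric tests (equivalent to
   one-sided Fisher's exact test) of HBS gene sets against a true-path
   propagated ontology, with Benjamini–Hochberg FDR control and removal of
   generic catch-all terms.

Because clinical aCGH data and a frozen interaction database cannot ship with
a package, `cnanet` includes a deterministic **synthetic-data generator**
(`simulate_study()`) that emulates every input — genome annotation, paired
CNA profiles, the interaction table, and ontology annotations — with planted
ground truth (recurrently gained cytobands, high-centrality regulators, one
enriched term), so the entire pipeline is testable end to end.

## Worked example

```r
library(cnanet)

dir <- file.path(tempdir(), "nb_study")
study <- simulate_study("small", seed = 42, dir = dir)  # writes all input files
res <- run_pipeline(dir)
res
```

```
<cnanet_pipeline>
CNA calls per sample/condition:
# A tibble: 6 × 5
  sample_id condition n_calls n_gains n_losses
1 P1        post            6       5        1
2 P1        pre             6       5        1
3 P2        post            6       2        4
...
Networks and HBS:
  sample_id condition n_nodes n_hubs n_bottlenecks n_switches n_hbs mean_degree
1 P1        post           81      6             5         10     5        8.94
2 P1        pre            81      6             5         15     5        8.99
...
3-way common HBS (pre): 5
3-way common HBS (post): 5
Global pre/post HBS intersection: 5
Enrichment (pre): 48 terms tested, 1 significant (q < 0.05)
```

Each patient/condition pair yields a network of ~80 proteins; the mean-degree,
mean-betweenness and mean-eigenvector thresholds each label a handful of
nodes, and their conjunction — 5 HBS per network — is exactly the set of
planted regulators, which is why all three patients share the same 5 HBS in
both conditions here. The top enriched term is the planted one:

```r
head(tibble::as_tibble(res$enrichment$pre), 3)
#   term_id  name                     k     K     N         p       q significant
# 1 SYN:0013 synthetic process 13     5    31   199 0.0000687 0.00344 TRUE
# 2 SYN:0005 synthetic process 05     5    67   199 0.00391   0.0977  FALSE
# 3 SYN:0027 synthetic process 27     2    27   199 0.137     1       FALSE
```

`k` of the study's 5 HBS genes are annotated to the term, out of `K` annotated
genes in the `N`-gene universe; `p` is the hypergeometric upper tail and `q`
its BH adjustment. Results are tibbles throughout, so they chain with the
pipe; `tidy()`/`glance()` methods summarise fitted objects and
`autoplot()`/`plot_cna_calls()` draw the standard figures.
`write_pipeline(res, out_dir)` emits byte-stable TSV/JSON reports.

A command-line front end over the same functions ships in
`inst/scripts/cnanet.R` (subcommands `simulate`, `pipeline`, `cna`,
`network`, `enrich`, `compare`).

## Scope

The package ingests segment-level CNA calls (a simplified TSV dialect of
aberration-interval reports); probe-level segmentation, dye normalization and
vendor binary formats are upstream of it. Networks are undirected and
unweighted; no community detection or weighted centralities. Enrichment is
classic one-sided Fisher/hypergeometric only — no elim/weight-style
decorrelation — and the ontology readers support plain child–parent TSVs and
a minimal OBO subset (`id`/`name`/`is_a`).
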