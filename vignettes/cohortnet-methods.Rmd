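---
title: "Methods: comparative mutation and network analysis of disease cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative mutation and network analysis of disease cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cohortnet)
```

cohortnet compares two point-mutation cohorts — typically a
neurodevelopmental-disorder (NDD) cohort of de novo germline variants and a
cancer cohort of somatic mutations — and asks how the same genes and
pathways can be hit in both while producing such different phenotypes. The
working hypothesis it operationalizes is quantitative: NDD mutations are
rare, weakly recurrent perturbations of the same signaling machinery that
cancer hits with frequent, strong driver mutations. The package turns that
hypothesis into four measurable layers: mutation recurrence, seeded network
inference, shared regulation, and pathway-level scoring.

## Mutation-catalog comparison

A catalog is a table of (sample, gene, protein change) records; protein
changes follow the short protein-HGVS grammar `^[A-Z]\d+([A-Z]|\*)$` after
stripping an optional `p.` prefix, so only single amino-acid substitutions
and nonsense changes are analyzed (`point_only` drops everything else and
reports the count). A sample carrying the same mutation in duplicate rows
counts once: all frequencies are per patient.

The recurrence of a mutation is `log10(N + 1)`, `N` the number of distinct
carriers. Two catalogs are compared by partitioning their unique mutations
into shared and cohort-specific sets and testing the two groups'
log-recurrence within a single reference cohort with a two-sided Welch
t-test. Welch was chosen over the pooled Student test because the groups
are routinely unbalanced in size and variance (a pooled variant and a
one-sided alternative sit behind flags). By default the comparison is
restricted to mutations actually observed in the reference cohort; an
`include_absent` flag scores absentees as zero instead. Degenerate inputs
are defined rather than left to error: two constant equal groups give
p = 1, two constant different groups give p = 0 with an infinite statistic.

Seed genes for network inference are those mutated in at least
`min_patients = 3` distinct samples, ordered by descending carrier count
with lexicographic tie-break so the list is reproducible under record
shuffling.

## Seeded network inference

The estimator `infer_disease_network()` runs three steps on a weighted
reference interactome (edge confidences in (0, 1]):

1. **Graphlet-guided network (GGN).** All connected induced subgraphs on
   2–4 nodes containing at least one seed are enumerated and classified
   into the nine connected graphlet types (edge, 3-path, triangle, 4-path,
   3-star, 4-cycle, tailed triangle, diamond, 4-clique). The enumeration is
   an ESU-style exclusive-neighborhood scheme in compiled code: each
   subgraph is emitted exactly once, with cross-seed ownership resolved by
   the smallest seed member. A type is *significant* when its seeded
   instance count exceeds the mean of `n_rewires = 100` degree-preserving
   rewirings by `z_threshold = 1.65` null standard deviations (one-sided
   empirical z, the conventional 5% normal cut). The GGN is the union of
   all seeded instances of significant types; if nothing is significant
   the GGN falls back to the seeds' incident edges with a warning. Because
   4-node enumeration around high-degree hubs can explode combinatorially,
   instances are reservoir-subsampled above `max_per_seed = 50000` per
   seed.

2. **Node and edge weighting.** Personalized PageRank solves
   `pr = (1 − α) r + α Mᵀ pr` with restart vector `r` uniform over the
   seeds and `M` the weight-normalized transition matrix of the undirected
   graph. `α = 0.5` is the probability of walking to a neighbor, so the
   restart probability is `1 − α = 0.5`. Isolated nodes carry an implicit
   self-loop, which leaves them exactly their restart mass and keeps the
   total mass at 1 (checked to 1e-12). Power iteration stops at an L1
   change below 1e-12; tests verify agreement with the direct
   linear-system solution to 1e-10. PageRank runs on the full reference
   network by default (`pagerank_scope = "ggn"` restricts it), because
   propagation through non-GGN paths still carries information about
   relative node relevance. Each edge is scored by flux: the directed flux
   `f(u→v) = pr(u)·w(u,v)/s(u)` (strength `s(u) = Σ w(u,·)`) is the
   PageRank mass `u` pushes across the edge in one step, and the edge score
   is the *minimum* of the two directions — a bottleneck convention under
   which an edge only scores high if both endpoints drive mass through it
   (`flux_mode = "sum"` gives the additive alternative). Fluxes are
   invariant to global weight rescaling.

3. **Selection.** GGN edges are ranked by flux (ties: higher min-endpoint
   PageRank, then lexicographic edge key, so the truncation is
   reproducible) and kept while the flux reaches the `τ = 0.8` quantile of
   the GGN flux distribution (type-7 quantile; τ = 0.8 keeps roughly the
   top 20% of edges), stopping at `edge_cap = 2000` edges. Raising τ can
   only shrink the selection; the cap and the subgraph nesting
   (network ⊆ GGN ⊆ interactome) are asserted on every tested run.

Where the source description of the method leaves "significant graphlet
motifs" and the τ selection rule unspecified, both are parameterized
(`z_threshold`, `n_rewires`, `tau`) with the defaults above.

## Shared regulation and overrepresentation

TFs of a regulatory map that appear as nodes of an inferred network are its
*specific transcription factors* (STFs); their regulated genes are the
union of their map targets (targets need not be network nodes). For two
networks, common TFs are the STF intersection and common targets are the
intersection of the two full STF-target unions — a gene regulated by
different TFs in the two diseases still counts; the stricter
"targets of common TFs only" semantics is a flag.

Common targets are tested against pathway gene sets (GMT) with the
hypergeometric upper tail `P(X ≥ k)` and Benjamini–Hochberg adjustment
across all tested sets; the significant view applies `p < 0.05` and
`FDR < 0.05`. The background universe defaults to the union of the
collection's genes and the query, is configurable, and is recorded in the
result — enrichment counts are only comparable under a fixed background.

## Pathway scoring

The expression score of pathway *P* in disease *d* is the mean absolute
differential-expression z-score of its genes, `ES_P = Σ|e_k| / n`: a
magnitude-of-deviation measure that is indifferent to the direction of the
change. Unmeasured genes are excluded from numerator and denominator (the
alternative, dividing by full pathway size, is `denominator = "pathway"`;
the exclusion default was chosen so sparse expression coverage does not
deflate the score). The propensity score `PS_P = Σ u_k / n` divides the
number of distinct (gene, protein change) mutations in the pathway by the
*full* pathway size — here the denominator is unambiguous ("per gene
member"), and `u_k` counts unique mutations, not carriers.

TF expression profiles across diseases are clustered by agglomerative
hierarchical clustering (Euclidean distance, average linkage, tree cut at
`k = 3`) — algorithm and metric are a package choice, parameterized, since
the source analysis specifies only "three groups". A TF is *differential*
against a reference disease when its z-score differs by at least
`delta = 1` (one z unit, configurable) from at least one other disease
with both values measured.

## The synthetic study generator

`simulate_study()` emits every pipeline input with known ground truth; its
defaults are the study conditions under which the package's guarantees are
tested:

* **Interactome** — preferential-attachment backbone over 2000 genes
  (3 edges per node), a planted 40-gene module wired at intra-module edge
  probability 0.3, Beta(5, 2) edge confidences. The module emulates the
  dense disease neighborhood that seeded inference should recover.
* **Cohorts** — 500 samples each. 25 cancer-like driver genes (80% from
  the module) with zero-truncated negative-binomial carrier counts of mean
  20 (dispersion 2, the over-dispersion seen in real recurrence data);
  300 NDD-like genes (10% module overlap) at mean 2 carriers; 2% of NDD
  unique mutations copied into the cancer catalog at NDD-like counts, so
  shared mutations are rare among tumors. These means give the Welch test
  on log-recurrence high power at the default sizes, mirroring the
  driver-versus-rare asymmetry the method exploits. Pathogenicity scores
  are Beta(8, 2) for driver records and Beta(4, 4) otherwise.
* **Regulation and pathways** — 50 overlapping gene sets of 20–80 genes;
  one planted TF draws ≥70% of its 30 targets from the planted pathway
  (whose size is raised, when necessary, to hold them); 39 background TFs
  (a quarter drawn from the module so networks contain TFs) target uniform
  random genes.
* **Expression** — per disease, z = N(0, 1) noise; planted-pathway genes
  shifted by ±Δ with a random sign per gene — Δ = 2.0 for the cancer-like
  disease, Δ = 0.5 for the NDD-like one — so that mean |z|, not mean z,
  separates strong from weak signaling. 10% of genes are unmeasured per
  disease.

Every output is a pure function of `(params, rng_seed)`; a master seed fans
out to per-stage child seeds through an integer recurrence so stages are
individually reproducible. What the generator does *not* emulate: real
mutational hotspot structure along protein sequences, gene-length and
expression-coverage biases, interactome study bias, or correlated pathway
membership. Passing tests therefore demonstrate that the machinery recovers
planted signals of realistic shape and size — not that the biological
conclusions transfer to any particular database snapshot. Headline counts
from specific database versions (network sizes, shared-mutation counts)
are version-bound and are not reproduction targets here.

## Problem sizes and numerical choices

The shipped checks run the generator at its defaults (2000 genes, ~6200
interactome edges, two 500-sample cohorts): 200 random graphs for the
PageRank oracle, 50 Erdős–Rényi graphs against brute-force subgraph
enumeration, 100 generator replicates for planted-signal recovery, 50
paired inference runs (true versus degree-matched random seeds, sign test)
for module recovery, and two full pipeline runs for byte-identical
determinism. Quantile type 7 (R's default) defines the τ cutoff;
empirical z uses the null standard deviation with a zero-sd guard (z = 0
when observed equals the degenerate null, ±Inf otherwise); BH adjustment
is `p.adjust(method = "BH")`; clustering ties follow `hclust`'s
deterministic merge order.

## Limitations

The interactome is treated as undirected and unsigned; regulatory mode
(activation/repression) is ignored; gene identifiers are matched by
uppercased symbol with no alias resolution; pathogenicity scores are
consumed as given, never computed; and the enrichment background, like any
ORA, determines the absolute significance levels — compare runs only under
the same universe.
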