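---
title: "Comparative co-expression analysis: model, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative co-expression analysis: model, parameters, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coexcompare)
```

## The model

`coexcompare` operationalizes a simple comparative principle: an association
between two genes that reappears independently in the co-expression networks
of several species is far more likely to be functionally real than one seen
in a single species. The unit of cross-species comparison is the *gene
family* (a homology group identifier shared by genes of all species, in the
style of PLAZA `HOM…` groups), because gene identifiers themselves are never
comparable across species. Orthology enters the analysis **only** through
shared family ids; no sequence analysis is performed here.

For S species networks, restricted to a pathway of interest by bait-centered
neighborhood extraction, we compute for every family F

> count(F) = number of networks containing at least one gene mapped to F,

an integer in 1..S. Within-network multiplicity is deliberately ignored: a
network with five peroxidase genes contributes exactly one "present" vote for
the peroxidase family, so count(F) measures cross-species recurrence, not
family size. The *conservation class* of a gene is count of its family (0 is
reserved for genes absent from the family map). The *conserved core* at
threshold m is the induced subgraph on genes of class ≥ m.

The *consensus network* abstracts from genes entirely: each species network
is collapsed to a family graph (edge F–G iff any gene of F is adjacent to any
gene of G; self-loop on F iff two *distinct* genes of F are adjacent — the
signature of intra-family transcriptional coordination, as when all cellulose
synthases of a complex are mutually co-expressed), and family pairs seen in
at least `min_edge_support` species are retained among families with
count ≥ `min_node_support`. Because it keeps only what recurs across extant
lineages, this graph can be read as a parsimony-flavored approximation of the
ancestral pathway network — hence the optional phylostratigraphy overlay,
which labels each family with the oldest clade of an ordered lineage series
in which it is recorded present.

## Assumptions and their limits

* **Topology only.** Input networks are treated as unweighted, undirected
  graphs; any weight column is ignored with a note. If your networks are
  thresholded differently per species, conservation counts inherit that
  inhomogeneity.
* **Family presence, not abundance.** count(F) is insensitive to how many
  genes of F occur in a network; this is intended (see above) but means a
  family kept alive by one marginal gene counts as much as a large conserved
  clique.
* **No statistics.** Counts are raw occurrences; no null model or p-value is
  attached to a conservation class or an edge support. With S = 4 networks
  the counts are too coarse for that to be meaningful.
* **Single-origin reading of lineage data.** A presence pattern
  (present, absent, present) is dated to the *oldest* presence; later
  absences are read as losses (Dollo-style). This is the simplest reading of
  first-appearance data and is not an ancestral-state reconstruction over a
  tree; clade order is user-supplied and never inferred.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `steps` | 2 | BFS radius around the baits (hops). 2 captures "neighbors of neighbors", the usual compromise between pathway coverage and noise. |
| `min_networks` | S | Conservation class needed for the conserved core (class = number of networks, unitless). |
| `min_node_support` | 3 | Families kept in the consensus. With four networks, 3 keeps families missing from at most one species. |
| `min_edge_support` | 3 | Species networks that must contain a family pair for it to be a consensus edge. The edge rule of published consensus figures is not uniquely determined, so this is a parameter (1..S) rather than a constant. |
| `target_bins` / `unknown_bins` | "10" / "35" | Top-level annotation bins counted as process-related / function-unknown (Mapman numbering: 10 = cell wall, 35 = unknown). |

Neighborhood extraction uses *induced-subgraph* semantics: all original edges
among collected genes are kept, including edges between two distance-2
genes. The alternative (keeping only BFS tree edges or bait-incident edges)
discards reproducible structure; published neighborhood figures display
edges among non-bait genes, which is only possible under induced semantics.
Multiple baits are a single multi-source search (distance = min over baits).

## The synthetic world

`generate_synthetic()` emulates the statistical structure the comparative
argument relies on, not the texture of real expression data:

* `n_species = 4` networks — mirroring a four-context comparison (two
  species × primary/secondary variants of a pathway counts as four networks).
* `n_core_families = 20` conserved families, `genes_per_family = 3`
  (within-network family redundancy is a documented feature of real cell-wall
  networks, e.g. several peroxidases per network).
* Core genes of one species form an Erdős–Rényi graph with
  `core_edge_prob = 0.3`; a *repair pass* then guarantees every core family
  has a gene within 2 steps of the bait family's genes, adding a minimal
  gene–bait edge when needed (logged in `repair_log`, so edge-probability
  properties can be tested pre-repair). Repair is what makes "the pipeline
  recovers the planted core exactly at zero noise" a theorem rather than a
  high-probability event.
* `n_noise_genes_per_species = 200` species-specific genes, each attached
  independently to every core node with `noise_edge_prob = 0.01` (and to one
  uniformly drawn core node if no attachment fires, so "noise gene" never
  degenerates to "isolated node"). Each noise gene carries its own
  single-species family: noise families are never forced to co-occur, which
  is precisely the comparative premise being modeled.
* Annotations: core genes draw the target bin with probability 0.9, else the
  unknown bin; noise genes draw from unrelated bins. The lineage table marks
  each core family present from a stratum sampled with weights
  (0.5, 0.4, 0.1) over (chlorophytes, mosses, angiosperms) — roughly half of
  a real conserved cell-wall core predates land plants and very little is
  angiosperm-novel — and noise families only in the newest clade.
* One integer seed drives a single RNG stream with a documented draw order
  (strata, then per species: core edges, repair, noise attachment; then
  annotations), so equal seeds give byte-identical bundles.

What a green synthetic test **does** establish: the operations compute what
they claim (they are checked against independent brute-force oracles), the
pipeline recovers a planted conserved core with precision/recall ≥ 0.9 under
1% noise, and the conservation-vs-relevance trend has the expected sign.
What it does **not** establish: behavior on real co-expression networks with
heavy-tailed degree distributions, correlated noise between related species,
families absent from the mapping, or expression-platform artifacts. Real
published numbers (neighborhoods of a few hundred genes in 20k–40k-gene
networks) depend on external PlaNet/PLAZA downloads; pointing the pipeline
config at those downloads with the PCW/SCW CESA baits is the corresponding
integration check and is intentionally outside the test suite.

## Numerical and degenerate-input choices

* Gene ids are case-sensitive opaque strings; families likewise. Genes
  missing from the family map are retained with the reserved family
  `"UNASSIGNED"` and class 0, so annotation tallies stay honest; `UNASSIGNED`
  never enters profiles, family graphs, or the consensus.
* Self-edges at the gene level are dropped with a warning (a gene cannot be
  co-expressed with itself); duplicate edges collapse. Singleton nodes are
  representable since a bait may have no neighbors.
* Category precedence in relevance tallies is target > unknown > other, and
  unannotated genes are "other", *not* "unknown" — "unknown" is an explicit
  annotation, absence of annotation is not. Hierarchical bins match by the
  prefix before the first dot. By default genes are counted once per network
  they occur in (the pooled-networks reading of class histograms);
  `dedupe = TRUE` switches to once per gene id, since the published
  aggregation rule is ambiguous — both modes are exposed.
* All writers emit canonically sorted rows, so identical inputs produce
  byte-identical outputs; determinism is part of the test contract.
* Ties and ordering: edge endpoints are sorted within a pair; profiles and
  reports sort by descending count then id.

## Known limitations

* Edge supports count networks, not within-network gene-pair multiplicity; a
  family pair connected by ten gene pairs in one species and one pair in
  another both contribute support 1 per species.
* `conservation_profile()` is evaluated on whatever networks you pass it —
  pass the extracted neighborhoods (as `run_pipeline()` does) rather than
  whole-genome networks, or counts describe the wrong universe.
* The consensus offers no significance filtering, and phylostratigraphy
  trusts the presence/absence table verbatim (including clade naming — the
  tool never resolves, say, chlorophytes vs charophytes).
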