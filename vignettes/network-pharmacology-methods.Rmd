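---
title: "Methods: network-pharmacology triage from screening to hub target"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: network-pharmacology triage from screening to hub target}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netpharm)
```

netpharm implements a desk-scale network-pharmacology workflow for drug
repurposing: given a roster of marketed compounds, predicted drug–target
tables from two sources, a disease-associated gene list, pathway
annotations and a protein–protein interaction (PPI) graph, it triages the
compounds down to a key pathway, a hub target and a ranked set of
candidate binders. This vignette explains each model, its assumptions,
the tunable parameters, and the design choices where the method left room
for judgement.

## Drug-likeness screening

Each compound carries SwissADME-style descriptors: molecular weight (MW,
g/mol), hydrogen-bond acceptor and donor counts (HBA, HBD), the Moriguchi
partition coefficient (MLogP) and topological polar surface area (TPSA,
Å²). `lipinski_violations()` counts failures of the four oral
drug-likeness bounds

* MW < 500, HBA < 10 (strict), and
* HBD ≤ 5, MLogP ≤ 4.15 (inclusive).

The mixed strict/inclusive boundary semantics are exactly the bounds as
tabulated by the descriptor profilers this roster format comes from; a
compound sitting on an inclusive bound passes, one sitting on a strict
bound fails. This is what lets the computed violation counts reproduce a
published violations column row for row rather than merely correlate with
it. `tpsa_filter()` applies the membrane-permeability rule TPSA < 140 Å²
(strict; the threshold is a parameter). Descriptors are taken from the
input table as-is — recomputing them from SMILES with another toolkit
shifts third decimals and would break exact reproduction, so no
recomputation path is used anywhere in the analyses.

Screening is annotative by default: all compounds proceed, carrying their
flags, because in the workflow this package reproduces no compound was
excluded at this stage. `screen(..., hard_filter = TRUE)` turns it into a
real filter.

## Two-stage target intersection

Gene identity is uppercase-symbol equality (`normalize_symbol()`): no
alias or HGNC resolution, because the inputs are plain symbol lists and
any resolution layer would make set cardinalities depend on an external
database version. `two_stage_overlap()` intersects the two
prediction-source target sets (stage 1), then intersects the survivors
with the disease set (stage 2). Outputs are sorted lexicographically so
reports are diffable; the raw union cardinality across both sources is
reported as a consistency check (|A| + |B| − |A∩B|).

## Pathway over-representation

For a query of $n$ genes against a pathway with background size $K$ drawn
from an $N$-gene universe, `enrich()` reports per pathway:

* the **rich factor** $k/K$, the fraction of the pathway hit by the
  query, computed at full precision and displayed at 4 decimals;
* a one-sided hypergeometric p-value $P(X \ge k)$,
  $X \sim \mathrm{Hypergeom}(N, K, n)$, via the log-space tail of
  `phyper` — the standard over-representation test family used by
  pathway-annotation servers, adopted here because the upstream analysis
  only names its annotation database, not its test;
* Benjamini–Hochberg FDR across the tested pathways (step-up with
  monotonicity enforcement, `p.adjust`), retained at `alpha = 0.05`.

$K$ always comes from the annotation (GMT member counts, or an explicit
size table when the GMT stores only the assayable subset), never from the
query: rich-factor denominators are annotation-wide. $N$ defaults to
20,000, the human protein-coding scale; it affects p-values but not rich
factors. `key_pathway()` selects the minimum-rich-factor row — among
significantly enriched pathways, the broad pathway touched most
selectively — with ties broken by smaller FDR, then lexicographic id.

One reference-table caveat: of the seven published enrichment rows only
four have an integer background size recoverable from the printed rich
factor (2/21, 3/64, 2/48, 4/330); the remaining rows contain printing
artefacts (a duplicated gene, an unmatchable ratio), so exact-arithmetic
checks cover the four recoverable rows and the rest are carried as data.

## Tripartite network and degree analysis

`build_pta()` builds the pathway–target–drug network with edges only
between adjacent layers; an identifier appearing in two layers is a
structure error. Entities with no surviving pair never enter the network,
which is how drugs whose targets all drop out of the final set disappear.
Degree (`degree_table()`) is the raw adjacency count — the published
degree discussion quotes integers — with per-layer breakdowns for target
nodes, since a target's pathway links and drug links are interpreted
separately.

## PPI hub isolation: the two-stage centrality filter

`isolate_hub()` implements the topological double filter:

1. rank the full PPI graph by degree centrality (DC) and keep the top
   30%;
2. build the induced subgraph on the survivors, recompute DC and
   betweenness centrality (BC) inside it, and keep the top 30% by BC.

Betweenness is shortest-path betweenness with pair dependencies split
equally among tied shortest paths, normalized by $(n-1)(n-2)/2$ so the
sole intermediary of a path graph scores exactly 1 — the normalization
under which the reference centrality tables print their hub at BC = 1.

The filter rule itself deserves a note, because "top 30%" alone is
ambiguous on small tables with ties and zeros. The rule implemented —
exclude metric-0 nodes first, select the top $\lceil f \cdot n \rceil$
where $n$ is the *original* table size, and include every node tied with
the boundary value — is the unique simple rule consistent with both
stages of the reference analysis (a 13-node table reducing to 5, then a
5-node table reducing to 1). Naive "top 30% with ties" or a plain ceiling
count each reproduce one stage but not the other. `zero_policy` and
`tie_policy` expose the alternatives.

Disconnected PPI nodes are kept with DC = BC = 0 (reference tables list
several), which is why `ppi_graph()` accepts a node roster alongside the
edge list.

A known limitation: the double filter can only find a hub that survives
the *degree* stage. In a planted-bridge graph with cliques of unequal
sizes, the stage-1 boundary tie falls inside the largest clique and the
smaller cliques are discarded wholesale, leaving a complete subgraph in
which every BC is 0 and no hub is isolated. The synthetic generator's
planted-hub shape therefore joins *equal-sized* cliques through a bridge
connected to every clique member: the bridge then dominates both degree
(sum of clique sizes) and betweenness (it carries every inter-clique
shortest path), and recovery is guaranteed. This is a property of the
method being reproduced, not of the implementation.

## Docking triage

The package never runs a docking engine — docking is external,
structure-dependent and nondeterministic — it prepares the engine's input
and consumes its output. `make_grid_config()` emits a deterministic
Vina-style config (receptor, ligand, grid-box center and size,
exhaustiveness 8, 10 poses, energy range 4 kcal/mol as defaults), with
numbers rendered at input precision so reruns are byte-identical.
`classify_binders()` applies the activity threshold: binding energy
strictly below −6.0 kcal/mol is active, a record exactly at −6.0 is not
(the threshold is quoted as a strict inequality where this workflow comes
from). `best_binder()` takes the energy minimum with a lexicographic
ligand-name tie-break. Typographic minus signs (U+2212) in parsed numbers
are normalized to ASCII, since published tables print them.

## Synthetic study generator

The generator exists so every stage is testable offline; its defaults
*are* the study conditions of the analysis this package reproduces:
prediction sources of 332 and 660 targets with a planted intersection of
198, a 622-gene disease set with a planted second-stage overlap of 15, a
32-compound roster, pathway size/hit pairs (21, 2), (64, 3), (48, 2),
(330, 4) spanning the published rich-factor range, and a 6-vs-2 docking
split around −6.0 kcal/mol. Planted cardinalities are exact by
construction (disjoint symbol-vocabulary pools with zero-padded
sequential names, `G000001…`), every generator is a pure function of its
seed and config (RNG state is saved and restored around each draw), and
the study writer emits files in the same dialects the readers parse, so
end-to-end tests exercise parsing as well as arithmetic.

What the generator does *not* emulate: real gene nomenclature and
aliasing, realistic chemistry (descriptors are drawn uniformly inside
marketed-antihistamine ranges), STRING-like confidence-score
distributions, or correlated structure between pathways and the PPI
graph. Passing tests therefore demonstrate that the pipeline's set
logic, statistics and graph topology are correct under controlled
structure — not that any particular biological conclusion transfers to
live database snapshots, which drift over time and are out of scope by
design.

## Numerical and degenerate-input choices

* Hypergeometric tails are computed in log space and agree with
  combinatorial enumeration to 10⁻¹² across all backgrounds up to
  N = 25 (tested exhaustively).
* An empty final target set is not an error: the pipeline reports the
  empty funnel, skips downstream stages with warnings and exits
  successfully.
* A query hitting no pathway yields an empty enrichment table with a
  warning; `key_pathway()` on an empty table is an error.
* An all-zero centrality table yields an empty selection with a warning,
  which propagates through `isolate_hub()` as an empty hub set.
* Edge lists drop self-loops (counted), collapse duplicate unordered
  pairs keeping the highest confidence, and treat a missing score column
  as confidence 1 — the analysis never states a confidence cutoff, so
  none is imposed by default.

## Problem sizes used in the test suite

The suite favours exhaustive checks at small sizes over sampled checks at
large ones: all hypergeometric tuples with N ≤ 25; all connected graphs
on ≤ 4 nodes plus all connected 5-node graphs in the acceptance
properties and sampled 6–7-node graphs elsewhere; 500 seeded
planted-bridge replicates for hub recovery; and 200 random configurations
for exact planted-cardinality recovery. These sizes make the oracles
(literal draw enumeration, depth-first path counting) affordable while
still covering every branch of the statistics they certify.

## Interface choice

The package is organised as an analysis workflow: the numbered scripts
under `analysis/` are thin narrative drivers over the exported functions,
and `run_pipeline()` orchestrates the full funnel from a single YAML
config. No shell-level CLI wrapper is provided; the functions, the
scripts and this vignette are the interface, which matches how the
analyses are actually re-run (from R, against files already on disk).
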