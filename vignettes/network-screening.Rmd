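---
title: "Topological screening of herb-component-target networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Topological screening of herb-component-target networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

```{r setup, message = FALSE}
library(netpharm)
library(igraph)
```

## The problem

Multi-herb formulas act through many components hitting many protein
targets at once. A standard way to dissect such a system is a chain of
network inferences: filter the formula's chemical constituents down to the
plausibly bioactive ones, map those to predicted protein targets, intersect
with disease-associated genes, grow protein-protein interaction (PPI)
subnetworks around both target sets over a background interactome, and
distil a *core target* set by topological screening, followed by dense-module
detection and functional enrichment. `netpharm` implements that whole chain
as ordinary R functions over igraph objects, with no live database access:
every external resource (component ADME tables, component-target
predictions, disease gene lists, the interactome, annotation gene sets)
enters as a plain text file.

## The screening model, stage by stage

### ADME bioactivity filter

Components are retained when oral bioavailability and drug-likeness both
clear their thresholds, **OB ≥ 20 %** and **DL ≥ 0.18** (both inclusive;
these are the conventional cutoffs for orally administered formulas).
Records with a missing OB or DL fail: the screen judges stated evidence
only. A `manual_keep` flag models curated retention of pharmacologically
established constituents — this is data, not algorithm, so the package
takes it as a table column rather than a hard-coded name list.

### Target sets and the bipartite network

Gene symbols are uppercased and trimmed before any set operation, because
disease databases mix case conventions; interactome node identifiers, by
contrast, are treated case-sensitively as opaque strings. The
component-target table becomes a bipartite network whose component-side
degrees rank *candidate components* (threshold: the interpolated median of
component degrees, or an explicit count).

### Seed expansion and network combination

`expand_seeds()` reproduces first-neighbour expansion: the subnetwork
induced on the seeds plus every node within `max_hops` (default 1) of a
seed, including neighbour-neighbour edges. Seeds missing from the
interactome are kept as isolated, role-tagged nodes so the loss is visible
rather than silent. The formula-side and disease-side subnetworks are then
combined; the default is **intersection** (nodes and edges supported by
both sides), since a joint network smaller than either input is only
coherent under intersection semantics. Union is available as an option.

### The two-stage core screen

Stage 1 keeps nodes with degree at least `multiplier` (default 2) times the
interpolated median degree — on any k-regular graph this is empty, which is
a useful sanity property. Stage 2 recomputes all six statistics **on the
stage-1 induced subnetwork** and requires each core node to *strictly*
exceed all six cutoffs simultaneously:

* **DC** — degree;
* **BC** — betweenness, unnormalized, over unordered pairs;
* **CC** — closeness, normalized to the reachable set
  ($cc(v) = r(v) / \sum_u d(v,u)$, 0 for isolated nodes);
* **EC** — eigenvector centrality, L2-normalized, scored on the largest
  connected component with zeros elsewhere (a principal eigenvector is
  ill-defined across components; per-component scoring is available);
* **LAC** — local average connectivity, the mean within-neighbourhood
  degree of a node's neighbours, computed as $2T(v)/\deg(v)$ with $T(v)$
  the triangle count at $v$;
* **NC** — summed edge clustering coefficients
  $ECC(u,v) = z_{uv} / \min(\deg u - 1, \deg v - 1)$ over incident edges,
  with a zero denominator giving 0 (the `(z+1)` variant is exposed as an
  option).

Published screens of this kind print their stage-2 cutoff values without
stating the generating rule; the package's default derives each cutoff as
that measure's median over the stage-1 subnetwork — the convention of the
topological-screening literature — and an explicit-cutoff mode accepts
published values verbatim. Recomputing on the reduced network matters: a
stage-2 degree cutoff can exceed the stage-1 entry cutoff only if degrees
are re-evaluated after reduction. Because stage-2 comparisons are strict,
a vertex-transitive stage-1 network yields an empty core: no node strictly
beats its own constant. Whether isolated nodes of the combined network
enter the medians is controlled by `drop_isolated` at the combination step
(dropped by default).

### MCODE clustering

`mcode()` implements molecular complex detection with the published
defaults: vertex weight = (highest k-core number) × (density of that core)
over the closed neighbourhood, for vertices of degree ≥ 2; greedy expansion
from the highest-weight unvisited seed admitting neighbours within
`node_score_cutoff` (VWP, default 0.2) of the seed weight; complexes
without a 2-core discarded; haircut (2-coring) on by default, fluff off.
Ties between equal-weight seeds break lexicographically by node name so
runs are deterministic — the reference implementation's order is arbitrary.
Cluster score is simple-graph density × size.

### Enrichment

`enrich()` computes the upper hypergeometric tail $P(X \ge k)$ for each
term via `stats::phyper`; EASE mode discounts one overlap member
($k \to k-1$, the conservative DAVID statistic). The Bonferroni multiplier
counts only terms with nonzero overlap (DAVID-style; the all-terms
multiplier is a flag away). The background defaults to the union of all
term sets and can be overridden, e.g. with the interactome size.
Significance filtering is strict (`<`), on adjusted p for GO-style use and
raw p for pathway-style use.

## What the synthetic generators emulate

Each generator plants a known structure and returns it as machine-readable
truth, so every pipeline stage has an exact expectation:

* `gen_components()` — per-herb tables with a controlled ADME pass
  fraction; OB of a passing record is uniform on [20, 60], DL on
  [0.18, 0.5]; failing records miss one criterion, both, or carry a
  missing value. These uniforms are stand-ins: no distributional claim is
  made about real ADME panels.
* `gen_component_target()` — component degrees from a truncated discrete
  power law (exponent 2.5 by default), rescaled to a requested mean:
  heavy-tailed promiscuity without modelling real chemistry.
* `gen_disease_targets()` — exactly `round(overlap_fraction × n)` members
  drawn from the formula-side target set, so the common-target count is
  known in advance; members are split across mock per-source lists whose
  union is the full list.
* `gen_interactome()` — a preferential-attachment backbone (complete-graph
  start, `m` edges per arrival, hence exactly $\binom{m}{2} + m(n-m)$
  backbone edges) with planted dense modules and hub nodes. Modules are
  planted on nodes non-adjacent to earlier modules: a single background
  edge between two planted cliques would make any density-based clusterer
  merge them, so separation is required for recovery against the truth to
  be a well-posed check.
* `gen_annotations()` — random term sets plus one spiked term
  over-represented in an emitted query at a stated strength.

The study preset (`write_synthetic_fixture()`) fixes the study
conditions at desk scale: 600 components across four herbs with pass
fraction 0.22 plus 9 manual keeps (141 bioactives, reading the published
count as inclusive of the curated retentions), 186 formula targets on a
1000-node, m = 3 interactome, a 546-gene disease list with overlap
fraction 52/546, two planted 8-cliques, one hub wired to 300 random nodes,
and a 50-term GMT with a 0.8-strength spike. A single pipeline seed fans
out to per-generator seeds, so one integer reproduces the whole fixture.

What passing on this fixture does **not** show: real interactomes have
richer degree correlations, annotation terms overlap hierarchically, and
real ADME values are anything but uniform. The generators validate the
*machinery* — counting, set algebra, induction, thresholds, recovery of
planted structure — not biological claims.

## Numerical choices

* Eigenvector centrality uses a deterministic shifted power iteration
  (iterating $A + I$), start vector uniform, convergence at max-norm
  change < 1e-10, error after 1000 iterations reporting the residual. The
  shift preserves the principal eigenvector while preventing the
  oscillation a plain iteration exhibits on bipartite components; a
  deterministic start keeps reruns byte-identical, which randomized
  ARPACK starts do not.
* Medians are the interpolated (`stats::median`) kind throughout.
* Edges are canonicalized as lexicographically sorted pairs; serialization
  order is therefore deterministic and write-read round-trips are exact
  set equalities.
* Self-loops and duplicate edges are dropped on ingestion with a logged
  count — the centralities and MCODE assume simple graphs.
* Degenerate inputs: an empty network passes through the screen (with a
  warning) and the pipeline completes with empty downstream artifacts —
  an empty result is distinguishable from an error.

## Problem sizes

The bundled analyses run at deliberately modest scale: the synthetic
interactome has 1000 nodes (~3300 edges), oracle comparisons use 200
random graphs of at most 15 nodes, and exhaustive enrichment enumeration
uses an 8-gene universe. These sizes make every expectation exactly
checkable (brute force, closed form, or planted truth) while the full test
suite and the end-to-end pipeline each run in well under a minute on one
CPU.

## A worked run

```{r}
fixdir <- file.path(tempdir(), "fixture")
fix <- write_synthetic_fixture(fixdir, seed = 42)
cfg <- pipeline_config(
  components  = file.path(fixdir, "components.tsv"),
  pairs       = file.path(fixdir, "pairs.tsv"),
  interactome = file.path(fixdir, "interactome.tsv"),
  disease_dir = file.path(fixdir, "disease"),
  gmt         = file.path(fixdir, "annotations.gmt"),
  out_dir     = file.path(tempdir(), "run"),
  seed        = 42)
report <- run_pipeline(cfg)
c(bioactive = report$components$bioactive,
  common    = report$targets$common,
  core      = report$core_screen$core_nodes)
```

## Known limitations

* No computation of OB/DL from structure, no target prediction, no
  database retrieval, no identifier-mapping service beyond a user-supplied
  two-column join — these are inputs by design.
* Unweighted, undirected graphs only.
* Information centrality is not provided; subgraph centrality is an
  optional extra (off by default) — the screening chain itself uses the
  six statistics above.
* Bonferroni is the only multiplicity control, matching the screening
  convention this chain follows; no FDR variants.
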