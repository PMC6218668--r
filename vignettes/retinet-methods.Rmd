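---
title: "Methods: network construction, centralities and disaggregation in retinet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: network construction, centralities and disaggregation in retinet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(retinet)
```

`retinet` turns a seven-table relational database of retinal diseases,
genes, phenotypes and proteins into undirected typed networks, measures
the topology that identifies hub genes, and quantifies the damage done
by removing a hub. This vignette records the model, the conventions
chosen where the underlying methodology is under-specified, and the
limits of what the package's tests demonstrate.

## The relational schema and the four network schemes

The database holds four entity tables (diseases with OMIM/DOID
identifiers, genes by symbol, phenotypes with HP identifiers, proteins
by accession) and three link tables (disease–gene, phenotype occurrence
in diseases, gene–protein). Identifiers are namespaced by vocabulary, so
node identities can never collide across kinds. Loading validates
referential integrity: duplicate link rows are dropped silently (the
graphs are simple), and unresolvable foreign keys either error
(`strict = TRUE`) or are dropped with a counted warning.

Four schemes project the tables onto networks:

1. **disease_gene** — one edge per association row; the backbone.
2. **protein_disease** — protein *p* joined to disease *d* whenever some
   gene links to both. The composition is keyed on the gene.
3. **disease_gene_by_phenotype** — a gene inherits the union of the
   phenotype annotations of its diseases; an edge (d, g) appears when
   that set intersects *d*'s own annotations. Whether pairs that are
   *also* direct associations belong in this network is genuinely open;
   they are retained by default (`retain_direct = FALSE` gives the
   strictly mediated variant).
4. **disease_phenotype_by_gene** — disease *d* joined to every phenotype
   occurring in a disease that shares at least one gene with *d*
   (including *d* itself); `direct_projection = TRUE` degrades this to
   one edge per occurrence row.

All networks are **undirected**: every centrality below presupposes
symmetric distances, and direction in the source material is a
presentation device of hierarchical layouts, not part of the model.
Entities without any edge are excluded unless `include_isolates = TRUE`.

## The centrality battery

All shortest paths are unweighted (breadth-first); nothing in the schema
provides edge weights.

**Topological coefficient.** For node *n* with degree $k_n$,
$T_n = \mathrm{avg}_m\, J(n,m) / k_n$ over all partners *m* that share at
least one neighbor with *n*, where $J(n,m)$ is the shared-neighbor count
plus one if *n* and *m* are adjacent. Conventions: $T_n = 0$ when
$k_n < 2$, and also when the partner set is empty (the source of the
formula is silent there; zero keeps the "no shared neighborhood" reading
consistent). $T_n$ is a local quantity — cheap on large graphs — and lies
in $[0, 1]$; values near 1 flag nodes whose neighborhoods are entirely
shared (small self-contained subnetworks), values near 0 on a
high-radiality node flag connectivity-holding hubs.

**Radiality.** $C_{rad}(v) = \sum_{w}(\Delta_G + 1 - d(v,w))/(n-1)$.
Two conventions matter on real databases, which are never connected:

- *Per-component evaluation.* Distances across components are infinite,
  so $n$, $\Delta_G$ and the sum are restricted to $v$'s component.
  Singleton components score 0.
- *Normalization.* The raw value exceeds 1 on any component with
  $\Delta_G \ge 2$; dividing by $\Delta_G$ maps it to $[0,1]$ with value
  exactly 1 for a node adjacent to every other node of its component.
  This is why nodes of two-node components rank at radiality 1.0: both
  endpoints are adjacent to everything they can reach. `rank_nodes()`
  exposes `min_component_size` for analysts who want such trivial
  components out of a hub table; it defaults to off, keeping every node.

**Betweenness.** The sum over unordered pairs $(s,t)$, both distinct
from $v$, of $\sigma_{st}(v)/\sigma_{st}$, normalized per component by
$(c-1)(c-2)/2$ — the pair count that makes the maximum (a path's middle
node between its only two other nodes, or a star center) exactly 1.
Whether published tables of this kind normalized per component or
globally is not determinable; per-component is used because it keeps the
measure comparable across components of different sizes.

**Centroid value.** The formula is not printed in the source
methodology, which only cites the computing plugin; the plugin's
standard definition is implemented, flagged here as an external
reconstruction: $C_{cen}(v) = \min_{w \ne v}(\gamma_v(w) - \gamma_w(v))$,
with $\gamma_v(w)$ the number of nodes strictly closer to $v$ than to
$w$, evaluated within the component. Positive values mark dominant
nodes, negative values dominated ones; ties count for neither side. The
computation is cubic in component size, so `centrality_table()` and
`disaggregate()` accept `centroid = FALSE` for very large graphs.

## Power-law fitting

Degree histograms (nodes per degree, isolates excluded) are fitted with
$y = a k^b$ by **unweighted least squares on $(\log k, \log y)$** — the
convention of the network-analyzer tools this workflow reproduces, "on
logarithmic values". Maximum-likelihood (Clauset-style) estimation,
$x_{min}$ truncation and alternative tail models are deliberately out of
scope: the fit is a hub-presence diagnostic, not a tail-index estimate.

Two association statistics are reported because they answer different
questions and can diverge dramatically: `r_squared` is the coefficient
of determination of the log–log regression (quality of the power-law
shape), while `correlation` is the Pearson correlation between observed
and fitted counts on the **original scale**, dominated by the
large-count head. The original-scale reading of "correlation" is itself
a reconstruction and is labelled as such wherever it is written out.

Degenerate inputs: fewer than two distinct degrees is an error; a
histogram with all counts equal has zero log-scale variance, and the fit
is reported as $b = 0$, $a = y$, both statistics 1, with a
`zero_variance` flag rather than an `NA` that would poison downstream
tables. Exactness: on noiseless power-law data the fit recovers $(a, b)$
to $10^{-9}$ relative tolerance with $r^2 = 1$ (asserted in the test
suite), and scaling all counts by $c$ scales $a$ by $c$ leaving $b$ and
$r^2$ unchanged.

The outlier experiment (`refit_without_node()`) removes one named node,
rebuilds the histogram and refits, returning both fits; a single extreme
degree class usually degrades a log–log fit, so the refit's $r^2$ is
expected to rise.

## Hub ranking and classification

`rank_nodes()` sorts a centrality table by one measure — radiality in
the reference workflow, with $T_n$ and betweenness as discriminator
columns — breaking ties by node id so rankings are reproducible.
The `interpretation` column encodes the reading of the $T_n$ extremes
($T_n \ge 0.9$: isolated subnetwork; $T_n \le 0.1$ with normalized
radiality $\ge 0.75$: integrity-holding hub); it is a label for human
readers, not a classification, and its two cutoffs are display
thresholds with no statistical claim attached.

`classify_nodes()` is the classification: *hub* when degree reaches a
threshold, *superhub* when a hub has at least two hub neighbors,
*peripheral* otherwise. No threshold is given by the source methodology;
the default is mean degree + 2 standard deviations, computed on the
network at hand, with absolute-degree and quantile rules as overrides,
and the threshold actually used is attached to the result so every run
is auditable. Under this rule, heavy-tailed degree distributions yield a
small hub set and — on the synthetic study conditions — no superhubs,
since hubs of preferential-attachment bipartite graphs are rarely within
two steps of each other (disassortativity).

`top_overlap()` compares hub tables across networks by label,
translating protein accessions to gene symbols through the gene–protein
table (proteins mapping to several genes contribute all symbols;
unmapped proteins are excluded with a warning).

## The disaggregation experiment

Removing a hub means removing its *selection*: the target, its
**topological twins**, and the first neighbors of that set. The twin
rule — nodes with exactly identical open neighborhoods — is the only
reading under which selecting one of two tightly-ligated nodes
necessarily selects the other; it is configurable off. Neighbor
expansion is fixed at depth one ("closest neighbors"); deeper expansion
has no support in the underlying protocol.

The report compares, before and after: node and edge counts, component
count, nodes left isolated (retained in the after-network and counted
both ways, since published counts of this experiment are ambiguous about
them; `drop_isolates = TRUE` removes them), the diameter of the largest
component, and the **mean centroid value over the largest component**.
Exact bookkeeping — `nodes_after + |removal set| + dropped isolates =
nodes_before` — is asserted on every run in the test suite.

One directional claim needed a decision. The expectation that the
network's average centroid value "diminishes" when a structurally
important node is subtracted cannot mean the signed mean decreases:
centroid values are negative for every node except the locally dominant
ones, so deleting the dominant hub *compresses* the distribution toward
zero and the signed mean typically rises. The package reads "diminish"
as a decrease in **magnitude** — the surviving network de-centralizes —
and that is the property asserted (at an 80%-of-seeds level across
20 seeded replicates) in the acceptance suite, for the full removal
experiment on the top-betweenness hub. Both signed values are reported
so either reading can be checked.

## The synthetic database generator

The generator emulates the statistical shape of a compiled
retinal-disease database so every stage is testable without downloads.
Defaults are the study conditions: 324 diseases, 803 genes, 463
phenotypes, 2461 proteins, 4 gene links per disease, target degree
exponent −1.655, 2–10 phenotype annotations per disease, 1–6 proteins
per gene, Zipf exponent 1.

- **Disease–gene links** are drawn by preferential attachment on gene
  popularity: each disease attaches `m` distinct genes with probability
  proportional to current gene degree plus a smoothing constant. The
  smoothing tunes the heaviness of the tail: large smoothing approaches
  uniform attachment, small smoothing lets early winners dominate. The
  constant is chosen from `target_exponent` through a measured monotone
  calibration (fitted log–log slope of the gene-side histogram versus
  smoothing, at ~2000 genes and m = 4, ten seeds per calibration point);
  targets outside the calibrated range of roughly [−2.1, −0.9] clamp to
  its ends. Recovery — the gene-side fitted slope landing within ±0.5
  (acceptance) and ±0.3 (module test) of the target in at least 90% of
  20 seeds at 2000 genes — is asserted by the test suite. Disease nodes
  all have degree exactly `m` by construction, which is why recovery is
  defined on the gene side.
- **Phenotype annotations** are sampled per disease without replacement
  under Zipf-like phenotype popularity ($w_r \propto r^{-s}$), giving
  the top-heavy occurrence table characteristic of real annotation data
  (top phenotype at least 3× the median count under the default, a
  property test).
- **Gene–protein relations** give every gene its minimum, then
  distribute the remaining proteins randomly within the per-gene cap, so
  protein totals are met exactly and every protein belongs to one gene.

All sampling is drawn, in documented order, from one Mersenne-Twister
stream seeded by `seed` (the caller's RNG state is untouched), so
identical parameters give byte-identical tables.

What the generator does **not** emulate: real OMIM/HPO semantics,
disease nosology, correlated phenotype co-annotation, genes shared
between biologically related diseases, or protein biology. Passing tests
therefore demonstrate that the pipeline's measurements and guarantees
hold on networks with the right *statistical shape* — heavy-tailed
degrees, skewed annotations, bipartite composition — not that any
biological conclusion about a particular gene transfers to real data.

## Problem sizes and numerical conventions

The test suite works at sizes chosen to keep the full run under a
minute while still exercising every regime: exhaustive brute-force
oracles (matrix-power distances, DFS shortest-path enumeration) on 200+
random graphs of up to 8 nodes; study-condition databases (324/803
entities, ~720-node networks) for end-to-end runs; 2000-gene networks,
20 seeds, for exponent recovery; 100-disease/250-gene networks, 20
seeds, for the centroid-shrinkage experiment (the cubic centroid
computation dominates there). `scripts/acceptance.R` re-runs all of the
above from one `--seed` in well under a minute.

Ties and determinism: every table is ordered by node id after the
primary sort key; edges are stored with lexicographically sorted
endpoints; identical configurations produce byte-identical artifact
files (asserted).

## Known limitations

- Centroid values are cubic in component size; on networks beyond a few
  thousand nodes per component they should be disabled or restricted to
  the subnetwork of interest.
- The power-law fit is a least-squares diagnostic on binned counts; it
  is biased as a tail-index estimator and should not be compared against
  maximum-likelihood exponents from other tools.
- The centroid-value formula and the original-scale "correlation"
  convention are reconstructions of under-documented upstream tools, and
  are labelled as such in outputs.
- SIF files cannot carry node labels (kind survives via the id prefix);
  GraphML or edge CSV + node table are lossless.
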