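# retinet

Network analysis of compiled retinal-disease databases: build
disease–gene, disease–phenotype and protein–disease networks from a
seven-table relational schema, measure the topology that reveals hub
genes, and quantify how the network falls apart when a hub is removed.

## The problem

Retinal diseases (retinitis pigmentosa and its many relatives) are
genetically and phenotypically heterogeneous: many genes cause the same
disease, many diseases share one gene. When diseases, genes, phenotypes
and proteins are compiled into one relational database, that
heterogeneity becomes a graph, and the genes holding the graph together
— the *hubs* — become candidates for targeted sequencing panels and
functional follow-up. `retinet` implements that workflow for anyone with
such a database (or no database at all: a seeded generator emulates one).

## What it computes

Four network schemes are projected from the tables: the direct
disease–gene network, a disease–gene network mediated by shared
phenotypes, a disease–phenotype network mediated by shared genes, and a
protein–disease network composed through gene–protein relations. On any
of them, per node *n* with degree *k<sub>n</sub>*:

- **Topological coefficient**
  *T<sub>n</sub> = avg(J(n, m)) / k<sub>n</sub>*, where *J(n, m)* counts
  shared neighbors of *n* and *m* plus one if they are linked, averaged
  over all partners *m* sharing at least one neighbor with *n*; nodes
  with fewer than two neighbors score 0.
- **Radiality**
  *C<sub>rad</sub>(v) = Σ<sub>w</sub> (Δ<sub>G</sub> + 1 − dist(v, w)) / (n − 1)*,
  with diameter Δ<sub>G</sub>, component size *n*, and a normalized
  variant dividing by Δ<sub>G</sub>.
- **Betweenness**
  *C<sub>spb</sub>(v) = Σ<sub>s≠t≠v</sub> σ<sub>st</sub>(v) / σ<sub>st</sub>*,
  normalized per component by (c−1)(c−2)/2.
- **Centroid value** min over *w* of γ<sub>v</sub>(w) − γ<sub>w</sub>(v),
  where γ<sub>v</sub>(w) counts nodes strictly closer to *v* than to *w*.

Degree distributions are fitted with *y = a·k<sup>b</sup>* by least
squares on log–log values (scale-free behavior signals the presence of
hubs), hubs are ranked with radiality as the ordering factor and
T<sub>n</sub>/betweenness as discriminators, nodes are classified
peripheral / hub / superhub by a degree threshold, and a *disaggregation
experiment* removes a highlighted node together with its topological
twins and first neighbors and reports the damage (nodes, edges, isolated
survivors, diameter, mean centroid value).

## Worked example

```r
library(retinet)

db  <- generate_db(synth_params(seed = 1))   # emulated database
net <- build_network(db, "disease_gene")
net
#> <bio_network: disease_gene> 720 nodes (324 disease / 396 gene / 0 phenotype / 0 protein), 1296 edges, 1 component(s)

fit_power_law(degree_distribution_table(net))
#> <power_law_fit> y = 318.2 * k^-1.792 on 20 degree classes
#>   r-squared (log-log) = 0.8167, correlation (original scale) = 0.4326

ct <- centrality_table(net, centroid = FALSE)
rank_nodes(ct, order_by = "radiality", k = 5, kind = "gene")[,
  c("node_id", "degree", "tn", "radiality_norm", "betweenness_norm",
    "interpretation")]
#> # A tibble: 5 × 6
#>   node_id degree     tn radiality_norm betweenness_norm interpretation
#>   <chr>    <int>  <dbl>          <dbl>            <dbl> <chr>
#> 1 RDG0574     55 0.024           0.777           0.310  integrity-holding hub
#> 2 RDG0642     27 0.0441          0.741           0.105  intermediate
#> 3 RDG0191     20 0.0545          0.727           0.0646 intermediate
#> 4 RDG0303     18 0.0667          0.714           0.0510 intermediate
#> 5 RDG0334     22 0.0545          0.711           0.0797 intermediate

genes  <- subset(ct, kind == "gene")
target <- genes$node_id[which.max(genes$betweenness_raw)]
disaggregate(net, target)
#> <disaggregation of 'RDG0574'> removed 56 node(s)
#>   nodes 720 -> 664 (25 isolated), edges 1296 -> 1076, components 1 -> 27
#>   largest-component mean centroid -593.875 -> -487.735, diameter 10 -> 12
```

Reading the ranking: a network whose degree histogram follows a power
law (r² ≈ 0.82 here) carries hubs. The top gene combines near-zero
T<sub>n</sub> with the highest radiality — the signature of a node that
holds the network together rather than sitting in a self-contained
subnetwork — and removing it with its neighborhood disconnects the graph
into 27 pieces with 25 isolated nodes, while the surviving core's mean
centroid value shrinks in magnitude (the network de-centralizes).

Real tables are loaded with `read_relational_db()` (seven CSV files;
delimiter and decimal mark configurable), networks are exchanged as SIF,
GraphML or edge CSV via `read_network()` / `write_network()`, and
`run_pipeline()` drives simulate / build / analyze / fit_powerlaw /
hubs / disaggregate steps from a serializable `run_config()`.

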