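# shared toy fixtures, built in code

toy_db <- function() {
  relational_db(
    diseases = data.frame(disease_id = c("D1", "D2"),
                          name = c("disease one", "disease two"),
                          abbrev = c("d1", "d2")),
    genes = data.frame(gene_id = c("G1", "G2", "G3"),
                       symbol = c("G1", "G2", "G3"),
                       location = c("1p1", "2q2", "3p3")),
    phenotypes = data.frame(phenotype_id = c("H1", "H2"),
                            name = c("phen one", "phen two")),
    proteins = data.frame(protein_id = c("P1", "P2"),
                          name = c("prot one", "prot two")),
    disease_gene = data.frame(disease_id = c("D1", "D1", "D2"),
                              gene_id = c("G1", "G2", "G2")),
    phenotype_occurrence = data.frame(disease_id = c("D1", "D2", "D1"),
                                      phenotype_id = c("H1", "H1", "H2")),
    related_proteins = data.frame(gene_id = c("G2", "G3"),
                                  protein_id = c("P1", "P2"))
  )
}

# quick builder for hand-drawn graphs: edges as c("a-b", "b-c")
make_net <- function(edge_spec, isolates = character()) {
  if (length(edge_spec)) {
    parts <- strsplit(edge_spec, "-", fixed = TRUE)
    edges <- tibble::tibble(from = vapply(parts, `[`, "", 1),
                            to = vapply(parts, `[`, "", 2))
  } else {
    edges <- tibble::tibble(from = character(), to = character())
  }
  ids <- sort(unique(c(edges$from, edges$to, isolates)))
  bio_network(tibble::tibble(id = ids, kind = "gene", label = ids), edges)
}

tiny_synth <- function(seed = 1, ...) {
  synth_params(n_diseases = 20, n_genes = 30, n_phenotypes = 15,
               n_proteins = 60, genes_per_disease_m = 2,
               phenotypes_per_disease = c(1, 4),
               proteins_per_gene = c(1, 4), seed = seed, ...)
}
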