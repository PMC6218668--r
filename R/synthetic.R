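#' Parameters for the synthetic database generator
#'
#' Defaults mirror the compiled retinal database the analysis targets:
#' 324 diseases, 803 genes, 463 phenotypes, 2461 proteins, about 4--5
#' gene associations per disease, and a disease--gene degree distribution
#' whose fitted log-log slope is near -1.655.
#'
#' @param n_diseases,n_genes,n_phenotypes,n_proteins entity counts.
#' @param genes_per_disease_m distinct genes attached to each disease.
#' @param target_exponent intended fitted slope `b` of the gene-side
#'   degree distribution (negative).  The preferential-attachment
#'   smoothing constant is calibrated to it (see [generate_db()]);
#'   targets outside roughly `[-2.1, -0.9]` are clamped to the calibrated
#'   range.
#' @param phenotypes_per_disease integer `c(min, max)` phenotype
#'   annotations per disease.
#' @param proteins_per_gene integer `c(min, max)` proteins per gene; the
#'   `n_proteins` total must be achievable within these bounds.
#' @param zipf_exponent skew of phenotype popularity (occurrence counts
#'   follow a Zipf-like rank distribution).
#' @param seed integer seed; identical parameters give identical output.
#' @return A validated list of class `synth_params`.
#' @export
synth_params <- function(n_diseases = 324, n_genes = 803,
                         n_phenotypes = 463, n_proteins = 2461,
                         genes_per_disease_m = 4, target_exponent = -1.655,
                         phenotypes_per_disease = c(2, 10),
                         proteins_per_gene = c(1, 6),
                         zipf_exponent = 1, seed = 1) {
  p <- list(n_diseases = n_diseases, n_genes = n_genes,
            n_phenotypes = n_phenotypes, n_proteins = n_proteins,
            genes_per_disease_m = genes_per_disease_m,
            target_exponent = target_exponent,
            phenotypes_per_disease = as.integer(phenotypes_per_disease),
            proteins_per_gene = as.integer(proteins_per_gene),
            zipf_exponent = zipf_exponent, seed = as.integer(seed))
  counts <- c(p$n_diseases, p$n_genes, p$n_phenotypes, p$n_proteins,
              p$genes_per_disease_m)
  if (any(counts < 1)) {
    abort("all entity counts and m must be >= 1", class = "retinet_param_error")
  }
  if (p$genes_per_disease_m > p$n_genes) {
    abort("genes_per_disease_m cannot exceed n_genes",
          class = "retinet_param_error")
  }
  for (rng in list(p$phenotypes_per_disease, p$proteins_per_gene)) {
    if (length(rng) != 2 || rng[1] < 1 || rng[1] > rng[2]) {
      abort("ranges must be c(min, max) with 1 <= min <= max",
            class = "retinet_param_error")
    }
  }
  if (p$phenotypes_per_disease[2] > p$n_phenotypes) {
    abort("phenotypes_per_disease max cannot exceed n_phenotypes",
          class = "retinet_param_error")
  }
  lo <- p$n_genes * p$proteins_per_gene[1]
  hi <- p$n_genes * p$proteins_per_gene[2]
  if (p$n_proteins < lo || p$n_proteins > hi) {
    abort(sprintf("n_proteins must lie in [%d, %d] for proteins_per_gene = c(%d, %d)",
                  lo, hi, p$proteins_per_gene[1], p$proteins_per_gene[2]),
          class = "retinet_param_error")
  }
  if (p$target_exponent >= 0) {
    abort("target_exponent must be negative", class = "retinet_param_error")
  }
  structure(p, class = "synth_params")
}

# Fitted log-log slope b as a function of the attachment smoothing
# constant, measured on preferential-attachment runs with ~2000 genes and
# m = 4; monotone, so the inverse map gives the smoothing for a target b.
pa_calibration <- data.frame(
  smoothing = c(0.05, 0.10, 0.15, 0.20, 0.30, 0.40, 0.60, 0.80,
                1.20, 1.60, 2.50),
  b = c(-0.834, -1.119, -1.324, -1.411, -1.606, -1.700, -1.844,
        -1.937, -2.049, -2.088, -2.138)
)

smoothing_for_exponent <- function(target) {
  stats::approx(x = pa_calibration$b, y = pa_calibration$smoothing,
                xout = target, rule = 2)$y
}

#' Generate a seeded synthetic relational database
#'
#' Emulates the statistical shape of a compiled disease database so the
#' whole pipeline is testable without any download:
#'
#' * disease--gene links are drawn by preferential attachment on gene
#'   popularity -- each disease attaches `m` distinct genes with
#'   probability proportional to the gene's current degree plus a
#'   smoothing constant, which tunes how heavy the resulting degree tail
#'   is and is calibrated from `target_exponent`;
#' * phenotype annotations use a Zipf-like phenotype popularity, so
#'   occurrence counts are top-heavy as in real annotation tables;
#' * every gene maps to at least one protein, protein totals exactly
#'   matching `n_proteins`.
#'
#' All randomness comes from one stream seeded with `params$seed` (the
#' caller's RNG state is untouched), and sampling order is fixed, so
#' identical parameters give byte-identical tables.
#'
#' @param params a [synth_params()].
#' @return A [relational_db()].
#' @export
generate_db <- function(params = synth_params()) {
  stopifnot(inherits(params, "synth_params"))
  withr::with_seed(params$seed, generate_db_impl(params))
}

generate_db_impl <- function(p) {
  diseases <- tibble(
    disease_id = sprintf("OMIM:%06d", 600000 + seq_len(p$n_diseases)),
    name = sprintf("SYNTHETIC RETINAL DISEASE %03d", seq_len(p$n_diseases)),
    abbrev = sprintf("SRD%03d", seq_len(p$n_diseases))
  )
  genes <- tibble(
    gene_id = sprintf("RDG%04d", seq_len(p$n_genes)),
    symbol = sprintf("RDG%04d", seq_len(p$n_genes)),
    location = sprintf("%d%s%d", sample(1:22, p$n_genes, replace = TRUE),
                       sample(c("p", "q"), p$n_genes, replace = TRUE),
                       sample(11:36, p$n_genes, replace = TRUE))
  )
  phenotypes <- tibble(
    phenotype_id = sprintf("HP:%07d", seq_len(p$n_phenotypes)),
    name = sprintf("SYNTHETIC PHENOTYPE %03d", seq_len(p$n_phenotypes))
  )
  proteins <- tibble(
    protein_id = sprintf("P%05d", seq_len(p$n_proteins)),
    name = sprintf("SYNTHETIC PROTEIN %04d", seq_len(p$n_proteins))
  )

  # disease-gene: preferential attachment on gene popularity
  s <- smoothing_for_exponent(p$target_exponent)
  deg <- numeric(p$n_genes)
  picks <- vector("list", p$n_diseases)
  for (i in seq_len(p$n_diseases)) {
    g <- sample.int(p$n_genes, p$genes_per_disease_m, prob = deg + s)
    deg[g] <- deg[g] + 1
    picks[[i]] <- g
  }
  disease_gene <- tibble(
    disease_id = rep(diseases$disease_id, each = p$genes_per_disease_m),
    gene_id = genes$gene_id[unlist(picks)]
  )

  # phenotype occurrence: Zipf-like popularity over phenotype ranks
  w <- seq_len(p$n_phenotypes)^(-p$zipf_exponent)
  rng <- p$phenotypes_per_disease
  n_ph <- sample(seq(rng[1], rng[2]), p$n_diseases, replace = TRUE)
  occ <- lapply(seq_len(p$n_diseases), function(i)
    sample.int(p$n_phenotypes, n_ph[i], prob = w))
  phenotype_occurrence <- tibble(
    disease_id = rep(diseases$disease_id, times = n_ph),
    phenotype_id = phenotypes$phenotype_id[unlist(occ)]
  )

  # proteins: every gene gets >= min, spare capacity filled at random
  rng <- p$proteins_per_gene
  n_per_gene <- rep(rng[1], p$n_genes)
  extra <- p$n_proteins - sum(n_per_gene)
  if (extra > 0) {
    slots <- rep(seq_len(p$n_genes), rng[2] - rng[1])
    chosen <- sample(slots)[seq_len(extra)]
    n_per_gene <- n_per_gene + tabulate(chosen, nbins = p$n_genes)
  }
  related_proteins <- tibble(
    gene_id = rep(genes$gene_id, times = n_per_gene),
    protein_id = proteins$protein_id
  )

  relational_db(diseases, genes, phenotypes, proteins, disease_gene,
                phenotype_occurrence, related_proteins, strict = TRUE)
}

#' Small deterministic reference graphs
#'
#' Canonical labelled toy graphs used as fixtures for the centrality
#' oracles: a path, a cycle, a star (first node is the center), a complete
#' graph, or a two-component graph (a triangle plus a path on the
#' remaining nodes; size 5 gives a triangle plus a single edge).
#'
#' @param kind one of `"path"`, `"cycle"`, `"star"`, `"complete"`,
#'   `"two_component"`.
#' @param size number of nodes (cycle needs >= 3, star >= 2,
#'   two_component >= 5).
#' @return A [bio_network()] with nodes `a`, `b`, `c`, ... of kind
#'   `gene`.
#' @export
generate_reference_graph <- function(kind = c("path", "cycle", "star",
                                              "complete", "two_component"),
                                     size) {
  kind <- match.arg(kind)
  size <- as.integer(size)
  min_size <- c(path = 1L, cycle = 3L, star = 2L, complete = 1L,
                two_component = 5L)
  if (size < min_size[[kind]]) {
    abort(sprintf("kind '%s' needs size >= %d", kind, min_size[[kind]]),
          class = "retinet_param_error")
  }
  ids <- if (size <= 26) letters[seq_len(size)] else
    sprintf("n%03d", seq_len(size))
  edges <- switch(kind,
    path = if (size > 1)
      tibble(from = ids[-size], to = ids[-1]) else
      tibble(from = character(), to = character()),
    cycle = tibble(from = ids, to = ids[c(2:size, 1)]),
    star = tibble(from = ids[1], to = ids[-1]),
    complete = if (size > 1) {
      pairs <- utils::combn(ids, 2)
      tibble(from = pairs[1, ], to = pairs[2, ])
    } else tibble(from = character(), to = character()),
    two_component = bind_rows(
      tibble(from = ids[c(1, 2, 1)], to = ids[c(2, 3, 3)]),
      tibble(from = ids[4:(size - 1)], to = ids[5:size])
    )
  )
  nodes <- tibble(id = ids, kind = "gene", label = ids)
  bio_network(nodes, edges, scheme = "custom")
}
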