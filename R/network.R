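#' Typed biological network
#'
#' A `bio_network` is a simple undirected graph whose nodes carry a `kind`
#' (`disease`, `gene`, `phenotype`, `protein`, or `unknown`) and a display
#' `label`.  It is stored as an [igraph][igraph::igraph-package] graph with
#' vertex attributes `kind` and `label` and graph attribute `scheme`, so
#' the whole igraph toolkit applies; the constructor guarantees there are
#' no self-loops or parallel edges.
#'
#' @param nodes data frame with columns `id`, `kind`, `label`.
#' @param edges data frame with columns `from`, `to` (node ids); duplicate
#'   edges (in either orientation) are dropped.
#' @param scheme optional scheme tag, one of [network_schemes()] or
#'   `"custom"`.
#' @return An object of classes `bio_network` and `igraph`.
#' @seealso [build_network()], [network_nodes()], [network_edges()],
#'   [network_summary()]
#' @export
bio_network <- function(nodes, edges, scheme = "custom") {
  nodes <- as_tibble(nodes)
  edges <- as_tibble(edges)
  stopifnot(all(c("id", "kind", "label") %in% names(nodes)),
            all(c("from", "to") %in% names(edges)))
  if (anyDuplicated(nodes$id)) abort("duplicate node ids")
  bad_kind <- setdiff(unique(nodes$kind), node_kinds)
  if (length(bad_kind)) {
    abort(paste0("unknown node kind(s): ", paste(bad_kind, collapse = ", ")))
  }
  loose <- setdiff(c(edges$from, edges$to), nodes$id)
  if (length(loose)) {
    abort(paste0("edge endpoint(s) not in node table: ",
                 paste(head(loose, 5), collapse = ", ")))
  }
  if (any(edges$from == edges$to)) abort("self-loops are not allowed")
  # canonical order: sorted endpoints within an edge, then lexicographic
  edges <- tibble(from = pmin(edges$from, edges$to),
                  to = pmax(edges$from, edges$to)) |>
    distinct() |>
    arrange(.data$from, .data$to)
  nodes <- arrange(nodes, .data$id)
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = nodes)
  g <- igraph::set_graph_attr(g, "scheme", scheme)
  class(g) <- c("bio_network", class(g))
  g
}

node_kinds <- c("disease", "gene", "phenotype", "protein", "unknown")

#' The four network schemes derivable from the database
#'
#' * `disease_gene` -- one edge per disease--gene association row.
#' * `disease_gene_by_phenotype` -- disease and gene joined when they are
#'   annotated with at least one common phenotype (a gene inherits the
#'   phenotypes of its associated diseases).
#' * `disease_phenotype_by_gene` -- disease joined to a phenotype occurring
#'   in any disease that shares at least one gene with it.
#' * `protein_disease` -- protein joined to every disease associated with
#'   one of the protein's genes.
#'
#' @return Character vector of the four scheme names.
#' @export
network_schemes <- function() {
  c("disease_gene", "disease_gene_by_phenotype",
    "disease_phenotype_by_gene", "protein_disease")
}

scheme_relation <- c(disease_gene = "dg",
                     disease_gene_by_phenotype = "dg_ph",
                     disease_phenotype_by_gene = "d_ph",
                     protein_disease = "pd",
                     custom = "link")

#' Project the relational database onto one of the four network schemes
#'
#' @param db a [relational_db()].
#' @param scheme one of [network_schemes()].
#' @param include_isolates keep entities of the scheme's two kinds that end
#'   up with no edge (default drops them).
#' @param retain_direct for `disease_gene_by_phenotype` only: keep
#'   phenotype-mediated edges that coincide with a direct disease--gene
#'   association (default `TRUE`); with `FALSE` only strictly mediated
#'   pairs remain.
#' @param direct_projection for `disease_phenotype_by_gene` only: if
#'   `TRUE`, emit one edge per occurrence row instead of the gene-sharing
#'   composition.
#' @return A [bio_network()].
#' @export
build_network <- function(db, scheme = network_schemes(),
                          include_isolates = FALSE, retain_direct = TRUE,
                          direct_projection = FALSE) {
  stopifnot(inherits(db, "relational_db"))
  scheme <- match.arg(scheme)

  edges <- switch(scheme,
    disease_gene = distinct(db$disease_gene, from = .data$disease_id,
                            to = .data$gene_id),
    protein_disease = db$related_proteins |>
      inner_join(db$disease_gene, by = "gene_id",
                 relationship = "many-to-many") |>
      distinct(from = .data$protein_id, to = .data$disease_id),
    disease_gene_by_phenotype = {
      # a gene's phenotype set = union over its diseases' phenotypes
      gene_phen <- db$disease_gene |>
        inner_join(db$phenotype_occurrence, by = "disease_id",
                   relationship = "many-to-many") |>
        distinct(.data$gene_id, .data$phenotype_id)
      e <- gene_phen |>
        inner_join(db$phenotype_occurrence, by = "phenotype_id",
                   relationship = "many-to-many") |>
        distinct(from = .data$disease_id, to = .data$gene_id)
      if (!retain_direct) {
        e <- anti_join(e, db$disease_gene,
                       by = c(from = "disease_id", to = "gene_id"))
      }
      e
    },
    disease_phenotype_by_gene = {
      if (direct_projection) {
        distinct(db$phenotype_occurrence, from = .data$disease_id,
                 to = .data$phenotype_id)
      } else {
        # diseases sharing >= 1 gene (a disease shares with itself)
        sharing <- db$disease_gene |>
          inner_join(db$disease_gene, by = "gene_id",
                     relationship = "many-to-many") |>
          distinct(disease_id = .data$disease_id.x,
                   partner = .data$disease_id.y)
        sharing |>
          inner_join(db$phenotype_occurrence,
                     by = c(partner = "disease_id"),
                     relationship = "many-to-many") |>
          distinct(from = .data$disease_id, to = .data$phenotype_id)
      }
    }
  )

  kinds <- switch(scheme,
    disease_gene = c("disease", "gene"),
    disease_gene_by_phenotype = c("disease", "gene"),
    disease_phenotype_by_gene = c("disease", "phenotype"),
    protein_disease = c("protein", "disease")
  )
  nodes <- bind_rows(
    tibble(id = db$diseases$disease_id, kind = "disease",
           label = db$diseases$name),
    tibble(id = db$genes$gene_id, kind = "gene", label = db$genes$symbol),
    tibble(id = db$phenotypes$phenotype_id, kind = "phenotype",
           label = db$phenotypes$name),
    tibble(id = db$proteins$protein_id, kind = "protein",
           label = db$proteins$name)
  ) |>
    filter(.data$kind %in% kinds)
  if (!include_isolates) {
    nodes <- filter(nodes, .data$id %in% c(edges$from, edges$to))
  }
  bio_network(nodes, edges, scheme = scheme)
}

#' Node and edge tables of a network
#'
#' @param net a [bio_network()].
#' @return `network_nodes()`: a tibble `id`, `kind`, `label`, `degree`;
#'   `network_edges()`: a tibble `from`, `to` in canonical order.
#' @export
network_nodes <- function(net) {
  stopifnot(inherits(net, "bio_network"))
  tibble(id = igraph::V(net)$name,
         kind = igraph::V(net)$kind,
         label = igraph::V(net)$label,
         degree = igraph::degree(net)) |>
    arrange(.data$id)
}

#' @rdname network_nodes
#' @export
network_edges <- function(net) {
  stopifnot(inherits(net, "bio_network"))
  if (igraph::ecount(net) == 0) {
    return(tibble(from = character(), to = character()))
  }
  e <- igraph::as_edgelist(net)
  tibble(from = pmin(e[, 1], e[, 2]), to = pmax(e[, 1], e[, 2])) |>
    arrange(.data$from, .data$to)
}

#' Summarise a network
#'
#' @param net a [bio_network()].
#' @return One-row tibble: total nodes, nodes per kind, edges, and number
#'   of connected components (0 for an empty network).
#' @export
network_summary <- function(net) {
  stopifnot(inherits(net, "bio_network"))
  kind <- igraph::V(net)$kind
  tibble(
    scheme = igraph::graph_attr(net, "scheme") %||% "custom",
    nodes = igraph::vcount(net),
    diseases = sum(kind == "disease"),
    genes = sum(kind == "gene"),
    phenotypes = sum(kind == "phenotype"),
    proteins = sum(kind == "protein"),
    edges = igraph::ecount(net),
    components = if (igraph::vcount(net) == 0) 0L else
      igraph::count_components(net)
  )
}

#' @method glance bio_network
#' @export
glance.bio_network <- function(x, ...) network_summary(x)

#' @export
print.bio_network <- function(x, ...) {
  s <- network_summary(x)
  cat(sprintf("<bio_network: %s> %d nodes (%d disease / %d gene / %d phenotype / %d protein), %d edges, %d component(s)\n",
              s$scheme, s$nodes, s$diseases, s$genes, s$phenotypes,
              s$proteins, s$edges, s$components))
  invisible(x)
}
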