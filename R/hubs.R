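measure_aliases <- c(
  tn = "tn", degree = "degree", centroid = "centroid",
  radiality = "radiality_norm", radiality_raw = "radiality_raw",
  radiality_norm = "radiality_norm",
  betweenness = "betweenness_norm", betweenness_raw = "betweenness_raw",
  betweenness_norm = "betweenness_norm"
)

resolve_measure <- function(records, measure) {
  if (!measure %in% names(measure_aliases)) {
    abort(sprintf("unknown measure '%s'; use one of: %s", measure,
                  paste(names(measure_aliases), collapse = ", ")),
          class = "retinet_usage_error")
  }
  col <- measure_aliases[[measure]]
  if (!col %in% names(records)) {
    abort(sprintf("records have no column '%s'", col),
          class = "retinet_usage_error")
  }
  col
}

#' Rank nodes by a centrality measure
#'
#' Orders a centrality table by one measure (radiality, in the reference
#' workflow, with the topological coefficient and betweenness kept as
#' discriminator columns) and keeps the top `k` rows.  Ties are broken by
#' `node_id` ascending, so the ranking is fully deterministic.
#'
#' An `interpretation` column annotates each row with the reading of its
#' Tn value: values near 1 indicate a self-contained subnetwork, values
#' near 0 combined with high radiality indicate an integrity-holding hub.
#' It is a label, not a classification (see [classify_nodes()] for the
#' degree-based classes).
#'
#' @param records a tibble from [centrality_table()].
#' @param order_by measure name: one of `tn`, `radiality`, `betweenness`,
#'   `degree`, `centroid` (or an explicit `_raw` / `_norm` column name).
#' @param k number of rows to keep.
#' @param kind optionally restrict to one node kind before ranking.
#' @param min_component_size optionally drop nodes in components smaller
#'   than this before ranking (e.g. 3 excludes trivial two-node
#'   components, which otherwise rank first on normalized radiality).
#' @return A tibble of `k` (or fewer) rows with an attribute `order_by`.
#' @export
rank_nodes <- function(records, order_by = "radiality", k = 10, kind = NULL,
                       min_component_size = NULL) {
  stopifnot(k >= 1)
  records <- as_tibble(records)
  col <- resolve_measure(records, order_by)
  if (!is.null(kind)) records <- filter(records, .data$kind %in% !!kind)
  if (!is.null(min_component_size) && "component_size" %in% names(records)) {
    records <- filter(records, .data$component_size >= min_component_size)
  }
  out <- records |>
    arrange(desc(.data[[col]]), .data$node_id) |>
    slice_head(n = k)
  if (all(c("tn", "radiality_norm") %in% names(out))) {
    out <- mutate(out, interpretation = dplyr::case_when(
      .data$tn >= 0.9 ~ "isolated subnetwork",
      .data$tn <= 0.1 & .data$radiality_norm >= 0.75 ~ "integrity-holding hub",
      TRUE ~ "intermediate"
    ))
  }
  attr(out, "order_by") <- col
  out
}

#' Map protein accessions to gene symbols
#'
#' Built from the gene--protein link table; proteins related to several
#' genes contribute all their symbols.
#'
#' @param db a [relational_db()].
#' @return A tibble `node_id` (protein accession), `label` (gene symbol).
#' @export
protein_gene_map <- function(db) {
  stopifnot(inherits(db, "relational_db"))
  db$related_proteins |>
    inner_join(db$genes, by = "gene_id") |>
    distinct(node_id = .data$protein_id, label = .data$symbol)
}

#' Labels shared between two hub tables
#'
#' Maps each table's nodes to labels (protein accessions are translated to
#' gene symbols through `label_map`, typically [protein_gene_map()]; other
#' nodes use their id) and intersects the two label sets -- the "repeated
#' genes on top of both networks" comparison.
#'
#' @param table_a,table_b non-empty tibbles with a `node_id` column
#'   (e.g. from [rank_nodes()]).
#' @param label_map optional tibble `node_id`, `label`; nodes of kind
#'   `protein` absent from the map are excluded with a warning.
#' @return Sorted character vector of shared labels.
#' @export
top_overlap <- function(table_a, table_b, label_map = NULL) {
  if (!nrow(table_a) || !nrow(table_b)) abort("hub tables must be non-empty")
  labels_of <- function(tab) {
    tab <- as_tibble(tab)[, intersect(c("node_id", "kind"), names(tab)),
                          drop = FALSE]
    if (is.null(label_map)) return(unique(tab$node_id))
    mapped <- inner_join(tab, label_map, by = "node_id")
    unmapped <- tab |>
      anti_join(label_map, by = "node_id")
    if ("kind" %in% names(unmapped)) {
      lost <- filter(unmapped, .data$kind == "protein")
      if (nrow(lost)) {
        warn(sprintf("%d protein node(s) without gene mapping excluded from overlap",
                     nrow(lost)))
      }
      unmapped <- filter(unmapped, .data$kind != "protein")
    }
    unique(c(mapped$label, unmapped$node_id))
  }
  sort(intersect(labels_of(table_a), labels_of(table_b)))
}

#' Coordinates for a centrality-vs-centrality scatterplot
#'
#' @param records a tibble from [centrality_table()].
#' @param x,y two *different* measure names (see [rank_nodes()] for the
#'   accepted names).
#' @return A tibble `node_id`, `x`, `y`, ordered by `node_id`, with
#'   attributes `x_measure` / `y_measure`.
#' @seealso [plot_centrality_scatter()]
#' @export
scatter_points <- function(records, x, y) {
  records <- as_tibble(records)
  cx <- resolve_measure(records, x)
  cy <- resolve_measure(records, y)
  if (cx == cy) {
    abort("x and y must be different measures", class = "retinet_usage_error")
  }
  out <- records |>
    transmute_scatter(cx, cy) |>
    arrange(.data$node_id)
  attr(out, "x_measure") <- cx
  attr(out, "y_measure") <- cy
  out
}

transmute_scatter <- function(records, cx, cy) {
  tibble(node_id = records$node_id, x = records[[cx]], y = records[[cy]])
}

#' Classify nodes as peripheral, hub or superhub
#'
#' A node is a *hub* when its degree reaches the threshold (by default the
#' mean degree plus two standard deviations, computed on the network being
#' classified), a *superhub* when it is a hub at least two of whose
#' neighbors are themselves hubs, and *peripheral* otherwise.  The
#' threshold actually used is attached to the result so runs are
#' auditable.
#'
#' @param net a [bio_network()].
#' @param rule threshold rule: `"mean_sd"` (mean + `value` standard
#'   deviations, default `value = 2`), `"absolute"` (degree `>= value`),
#'   or `"quantile"` (degree `>=` the `value` quantile, e.g. 0.95).
#' @param value rule parameter (see above); default 2 for `mean_sd`.
#' @param min_hub_neighbors hub neighbors needed for superhub status.
#' @return A tibble `node_id`, `degree`, `class` (factor peripheral <
#'   hub < superhub), with attribute `hub_threshold`.
#' @export
classify_nodes <- function(net, rule = c("mean_sd", "absolute", "quantile"),
                           value = NULL, min_hub_neighbors = 2) {
  stopifnot(inherits(net, "bio_network"))
  rule <- match.arg(rule)
  deg <- igraph::degree(net)
  if (length(deg) == 0) {
    out <- tibble(node_id = character(), degree = integer(),
                  class = factor(character(),
                                 levels = c("peripheral", "hub", "superhub")))
    attr(out, "hub_threshold") <- NA_real_
    return(out)
  }
  thr <- switch(rule,
    mean_sd = mean(deg) + (value %||% 2) * (if (length(deg) > 1) sd(deg) else 0),
    absolute = value %||% abort("rule 'absolute' needs a value"),
    quantile = quantile(deg, value %||% abort("rule 'quantile' needs a value"),
                        names = FALSE)
  )
  is_hub <- deg >= thr
  A <- igraph::as_adjacency_matrix(net, sparse = TRUE)
  hub_nb <- as.numeric(A %*% as.numeric(is_hub))
  cls <- ifelse(!is_hub, "peripheral",
                ifelse(hub_nb >= min_hub_neighbors, "superhub", "hub"))
  out <- tibble(node_id = igraph::V(net)$name,
                degree = as.integer(deg),
                class = factor(cls, levels = c("peripheral", "hub", "superhub"))) |>
    arrange(.data$node_id)
  attr(out, "hub_threshold") <- unname(thr)
  out
}
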