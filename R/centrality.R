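#' Shared-neighbor score between two nodes
#'
#' The building block of the topological coefficient: the number of
#' neighbors two distinct nodes have in common, plus one if they are
#' directly linked.
#'
#' @param net a [bio_network()].
#' @param n,m distinct node ids present in `net`.
#' @return Integer score `|N(n) \U2229 N(m)| + [n ~ m]`.
#' @export
shared_neighbor_score <- function(net, n, m) {
  stopifnot(inherits(net, "bio_network"))
  ids <- igraph::V(net)$name
  if (!n %in% ids || !m %in% ids) abort("node not present in network")
  if (n == m) abort("nodes must be distinct")
  nb_n <- igraph::neighbors(net, n)$name
  nb_m <- igraph::neighbors(net, m)$name
  length(intersect(nb_n, nb_m)) + as.integer(m %in% nb_n)
}

# all-node topological coefficients via sparse matrix algebra:
# S = A^2 holds shared-neighbor counts; partners of n are the m != n with
# S[n, m] > 0, and J(n, m) = S[n, m] + A[n, m]
tn_all <- function(net) {
  nv <- igraph::vcount(net)
  deg <- igraph::degree(net)
  tn <- numeric(nv)
  if (nv == 0 || igraph::ecount(net) == 0) return(tn)
  A <- igraph::as_adjacency_matrix(net, sparse = TRUE)
  S <- A %*% A
  tri <- Matrix::summary(S)
  tri <- tri[tri$i != tri$j, , drop = FALSE]
  if (nrow(tri)) {
    J <- tri$x + A[cbind(tri$i, tri$j)]
    avg <- vapply(split(J, factor(tri$i, levels = seq_len(nv))), function(v) {
      if (length(v)) mean(v) else 0
    }, numeric(1))
    ok <- deg >= 2
    tn[ok] <- avg[ok] / deg[ok]
  }
  tn
}

#' Topological coefficient
#'
#' For a node with `k >= 2` neighbors, the mean [shared_neighbor_score()]
#' over all partner nodes (those sharing at least one neighbor with it),
#' divided by `k`.  Nodes with fewer than two neighbors -- and nodes with
#' no partner at all -- score zero.  Values lie in `[0, 1]`; values near 1
#' flag tightly shared neighborhoods (small self-contained subnetworks),
#' values near 0 with high radiality flag integrity-holding hubs.
#'
#' @param net a [bio_network()].
#' @param node a node id, or `NULL` for all nodes.
#' @return A named numeric vector (all nodes, sorted by id) or a single
#'   value.
#' @export
topological_coefficient <- function(net, node = NULL) {
  stopifnot(inherits(net, "bio_network"))
  vals <- setNames(tn_all(net), igraph::V(net)$name)
  pick_node(vals, node)
}

pick_node <- function(vals, node) {
  if (is.null(node)) return(vals[order(names(vals))])
  if (!node %in% names(vals)) abort("node not present in network")
  unname(vals[node])
}

# per-component geometry shared by radiality / centroid / normalizers
component_info <- function(net) {
  comp <- igraph::components(net)
  list(membership = comp$membership, sizes = comp$csize,
       ids = igraph::V(net)$name)
}

#' Radiality centrality
#'
#' Sums `diameter + 1 - dist(v, w)` over all nodes `w` reachable from `v`
#' and averages over the `n - 1` other nodes of v's connected component
#' (component size and diameter are used: distances across components are
#' never summed).  The normalized value divides by the component diameter,
#' so a node adjacent to every other node of its component scores 1.
#' Singleton components score 0.
#'
#' @param net a [bio_network()].
#' @param node a node id, or `NULL` for all nodes.
#' @param normalized return the `[0, 1]` normalized value (default) or the
#'   raw average in distance units.
#' @return A named numeric vector or a single value.
#' @export
radiality <- function(net, node = NULL, normalized = TRUE) {
  stopifnot(inherits(net, "bio_network"))
  r <- radiality_all(net)
  vals <- if (normalized) r$norm else r$raw
  pick_node(setNames(vals, igraph::V(net)$name), node)
}

radiality_all <- function(net, dist = NULL) {
  nv <- igraph::vcount(net)
  raw <- norm <- numeric(nv)
  if (nv == 0) return(list(raw = raw, norm = norm))
  ci <- component_info(net)
  if (is.null(dist)) dist <- igraph::distances(net)
  for (c_id in seq_along(ci$sizes)) {
    idx <- which(ci$membership == c_id)
    n <- length(idx)
    if (n < 2) next
    d <- dist[idx, idx, drop = FALSE]
    diam <- max(d)
    raw[idx] <- (rowSums(diam + 1 - d) - (diam + 1)) / (n - 1)
    norm[idx] <- raw[idx] / diam
  }
  list(raw = raw, norm = norm)
}

#' Shortest-path betweenness centrality
#'
#' Fraction of shortest paths between node pairs that pass through a node:
#' the sum over unordered pairs `(s, t)` (both distinct from `v`) of
#' `sigma_st(v) / sigma_st`.  The normalized value divides by
#' `(c - 1)(c - 2) / 2` where `c` is the size of v's connected component,
#' mapping it to `[0, 1]`.
#'
#' @param net a [bio_network()].
#' @param node a node id, or `NULL` for all nodes.
#' @param normalized normalize per component (default).
#' @return A named numeric vector or a single value.
#' @export
betweenness_centrality <- function(net, node = NULL, normalized = TRUE) {
  stopifnot(inherits(net, "bio_network"))
  b <- betweenness_all(net)
  vals <- if (normalized) b$norm else b$raw
  pick_node(setNames(vals, igraph::V(net)$name), node)
}

betweenness_all <- function(net) {
  nv <- igraph::vcount(net)
  if (nv == 0) return(list(raw = numeric(0), norm = numeric(0)))
  raw <- igraph::betweenness(net, directed = FALSE, normalized = FALSE)
  ci <- component_info(net)
  csize <- ci$sizes[ci$membership]
  denom <- (csize - 1) * (csize - 2) / 2
  norm <- ifelse(denom > 0, raw / denom, 0)
  list(raw = unname(raw), norm = unname(norm))
}

#' Centroid value
#'
#' For each pair of nodes `(v, w)` in the same component let `gamma_v(w)`
#' be the number of nodes strictly closer to `v` than to `w`.  The
#' centroid value of `v` is `min over w != v of gamma_v(w) - gamma_w(v)`:
#' positive values mark nodes sitting in a dense region they dominate,
#' negative values peripheral nodes.  Nodes in singleton components are
#' reported as 0 with a warning.
#'
#' @param net a [bio_network()].
#' @param node a node id, or `NULL` for all nodes.
#' @return A named numeric (integer-valued) vector or a single value.
#' @export
centroid_value <- function(net, node = NULL) {
  stopifnot(inherits(net, "bio_network"))
  vals <- centroid_all(net)
  pick_node(setNames(vals, igraph::V(net)$name), node)
}

centroid_all <- function(net, dist = NULL, warn_singleton = TRUE) {
  nv <- igraph::vcount(net)
  out <- numeric(nv)
  if (nv == 0) return(out)
  ci <- component_info(net)
  if (any(ci$sizes == 1) && warn_singleton) {
    warn("centroid value undefined for singleton components; reported as 0")
  }
  if (is.null(dist)) dist <- igraph::distances(net)
  for (c_id in seq_along(ci$sizes)) {
    idx <- which(ci$membership == c_id)
    n <- length(idx)
    if (n < 2) next
    d <- dist[idx, idx, drop = FALSE]
    # G[v, w] = #{u in component : d(u, v) < d(u, w)}
    G <- matrix(0L, n, n)
    for (w in seq_len(n)) G[, w] <- colSums(d < d[w, ])
    f <- G - base::t(G)
    diag(f) <- NA
    out[idx] <- apply(f, 1, min, na.rm = TRUE)
  }
  out
}

#' Per-node centrality battery
#'
#' Computes, for every node, the topological coefficient, raw and
#' normalized radiality, raw and normalized betweenness, centroid value,
#' degree and component size, in one pass over the shortest-path matrix.
#'
#' @param net a [bio_network()].
#' @param centroid include the centroid value (cubic in component size;
#'   set `FALSE` to skip on very large graphs).
#' @return A tibble with one row per node, ordered by `node_id`.
#' @export
centrality_table <- function(net, centroid = TRUE) {
  stopifnot(inherits(net, "bio_network"))
  nv <- igraph::vcount(net)
  if (nv == 0) {
    return(tibble(node_id = character(), kind = character(),
                  label = character(), degree = integer(),
                  component_size = integer(), tn = numeric(),
                  radiality_raw = numeric(), radiality_norm = numeric(),
                  betweenness_raw = numeric(), betweenness_norm = numeric(),
                  centroid = numeric()))
  }
  dist <- igraph::distances(net)
  ci <- component_info(net)
  rad <- radiality_all(net, dist = dist)
  btw <- betweenness_all(net)
  tibble(
    node_id = igraph::V(net)$name,
    kind = igraph::V(net)$kind,
    label = igraph::V(net)$label,
    degree = as.integer(igraph::degree(net)),
    component_size = as.integer(ci$sizes[ci$membership]),
    tn = tn_all(net),
    radiality_raw = rad$raw,
    radiality_norm = rad$norm,
    betweenness_raw = btw$raw,
    betweenness_norm = btw$norm,
    centroid = if (centroid) centroid_all(net, dist = dist,
                                          warn_singleton = FALSE) else NA_real_
  ) |>
    arrange(.data$node_id)
}

#' Degree-class distributions of clustering and neighborhood connectivity
#'
#' The local clustering coefficient of a node is
#' `2 e_N / (k (k - 1))` where `e_N` counts edges among its `k` neighbors
#' (0 when `k < 2`); neighborhood connectivity is the mean degree of a
#' node's neighbors.  Both are averaged within each degree class, giving
#' the two distribution curves used to assess hub structure.
#'
#' @param net a [bio_network()].
#' @return A list of two tibbles, `clustering` (`degree`,
#'   `avg_clustering`) and `connectivity` (`degree`,
#'   `avg_neighbor_degree`), over degree classes `>= 1`.
#' @export
clustering_connectivity_distributions <- function(net) {
  stopifnot(inherits(net, "bio_network"))
  deg <- igraph::degree(net)
  keep <- deg >= 1
  if (!any(keep)) {
    return(list(clustering = tibble(degree = integer(),
                                    avg_clustering = numeric()),
                connectivity = tibble(degree = integer(),
                                      avg_neighbor_degree = numeric())))
  }
  cc <- igraph::transitivity(net, type = "localundirected", isolates = "zero")
  cc[is.na(cc)] <- 0
  A <- igraph::as_adjacency_matrix(net, sparse = TRUE)
  nbdeg <- as.numeric(A %*% deg)
  nbdeg[keep] <- nbdeg[keep] / deg[keep]
  df <- tibble(degree = as.integer(deg[keep]), cc = cc[keep],
               nc = nbdeg[keep])
  list(
    clustering = df |> group_by(.data$degree) |>
      summarise(avg_clustering = mean(.data$cc), .groups = "drop") |>
      arrange(.data$degree),
    connectivity = df |> group_by(.data$degree) |>
      summarise(avg_neighbor_degree = mean(.data$nc), .groups = "drop") |>
      arrange(.data$degree)
  )
}
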