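#' Topological twins of a node
#'
#' Under the default rule, a twin of `v` is any other node with exactly
#' the same open neighborhood -- the configuration in which selecting one
#' node necessarily selects the other, because the two are
#' indistinguishable to the rest of the network.
#'
#' @param net a [bio_network()].
#' @param node a node id.
#' @param rule `"identical_neighborhood"` or `"none"` (no twins).
#' @return Character vector of twin node ids (possibly empty).
#' @export
node_twins <- function(net, node, rule = c("identical_neighborhood", "none")) {
  stopifnot(inherits(net, "bio_network"))
  rule <- match.arg(rule)
  ids <- igraph::V(net)$name
  if (!node %in% ids) abort("node not present in network")
  if (rule == "none") return(character())
  nb_v <- sort(igraph::neighbors(net, node)$name)
  cand <- setdiff(unique(unlist(lapply(nb_v, function(w)
    igraph::neighbors(net, w)$name))), node)
  cand[vapply(cand, function(w)
    identical(sort(igraph::neighbors(net, w)$name), nb_v), logical(1))]
}

#' Nodes co-removed with a disaggregation target
#'
#' The removal set is the target, its twins (see [node_twins()]), and --
#' when `include_neighbors` is set -- the first neighbors of that expanded
#' selection (expansion depth is fixed at one).
#'
#' @param net a [bio_network()].
#' @param target a node id.
#' @param include_neighbors expand the selection to its first neighbors.
#' @param twin_rule passed to [node_twins()].
#' @return Character vector of node ids, always containing `target`.
#' @export
removal_set <- function(net, target, include_neighbors = TRUE,
                        twin_rule = c("identical_neighborhood", "none")) {
  stopifnot(inherits(net, "bio_network"))
  core <- c(target, node_twins(net, target, rule = twin_rule))
  if (include_neighbors) {
    nb <- unique(unlist(lapply(core, function(v)
      igraph::neighbors(net, v)$name)))
    core <- union(core, nb)
  }
  sort(unique(core))
}

#' Disaggregation experiment: subtract a node and measure the damage
#'
#' Removes the [removal_set()] of `target` from the network and compares
#' topology before and after: node / edge / component counts, nodes left
#' isolated by the removal, the diameter of the largest component, and the
#' mean centroid value over the largest component (the summary that is
#' expected to diminish when a node of structural importance is
#' subtracted).  Isolated survivors are retained in the after-network and
#' counted; both counting modes (with and without them) are reported, and
#' `drop_isolates = TRUE` removes them from the returned network as well.
#'
#' @param net a [bio_network()].
#' @param target a node id.
#' @inheritParams removal_set
#' @param drop_isolates also delete nodes left with degree 0.
#' @param centroid compute the mean-centroid fields (cubic in component
#'   size; set `FALSE` to skip).
#' @return An object of class `disaggregation` with elements `after` (the
#'   reduced [bio_network()]) and `report` (a one-row tibble); [glance()]
#'   returns the report, [tidy()] the removal set.
#' @export
disaggregate <- function(net, target, include_neighbors = TRUE,
                         twin_rule = c("identical_neighborhood", "none"),
                         drop_isolates = FALSE, centroid = TRUE) {
  stopifnot(inherits(net, "bio_network"))
  rm_set <- removal_set(net, target, include_neighbors = include_neighbors,
                        twin_rule = twin_rule)
  after <- igraph::delete_vertices(net, rm_set)
  class(after) <- class(net)
  deg_after <- igraph::degree(after)
  isolated <- names(deg_after)[deg_after == 0]
  dropped <- 0L
  if (drop_isolates && length(isolated)) {
    after <- igraph::delete_vertices(after, isolated)
    class(after) <- class(net)
    dropped <- length(isolated)
  }

  report <- tibble(
    target = target,
    removal_set = list(rm_set),
    nodes_before = igraph::vcount(net),
    nodes_after = igraph::vcount(after),
    nodes_after_excl_isolated = igraph::vcount(after) -
      if (drop_isolates) 0L else length(isolated),
    isolated_after = length(isolated),
    isolates_dropped = dropped,
    edges_before = igraph::ecount(net),
    edges_after = igraph::ecount(after),
    components_before = n_components(net),
    components_after = n_components(after),
    diameter_before = largest_component_diameter(net),
    diameter_after = largest_component_diameter(after),
    mean_centroid_before = if (centroid) mean_centroid(net) else NA_real_,
    mean_centroid_after = if (centroid) mean_centroid(after) else NA_real_
  )
  structure(list(after = after, report = report), class = "disaggregation")
}

n_components <- function(net) {
  if (igraph::vcount(net) == 0) 0L else igraph::count_components(net)
}

largest_component_diameter <- function(net) {
  if (igraph::vcount(net) == 0) return(NA_integer_)
  comp <- igraph::components(net)
  idx <- which(comp$membership == which.max(comp$csize))
  sub <- igraph::induced_subgraph(net, idx)
  if (igraph::vcount(sub) < 2) return(0L)
  as.integer(igraph::diameter(sub, directed = FALSE))
}

#' Mean centroid value over the largest connected component
#'
#' @param net a [bio_network()].
#' @return Mean of [centroid_value()] over the nodes of the largest
#'   component; 0 for an empty network or a singleton largest component.
#' @export
mean_centroid <- function(net) {
  stopifnot(inherits(net, "bio_network"))
  if (igraph::vcount(net) == 0) return(0)
  comp <- igraph::components(net)
  idx <- which(comp$membership == which.max(comp$csize))
  if (length(idx) < 2) return(0)
  sub <- igraph::induced_subgraph(net, idx)
  class(sub) <- class(net)
  mean(centroid_all(sub, warn_singleton = FALSE))
}

#' @method glance disaggregation
#' @export
glance.disaggregation <- function(x, ...) x$report

#' @method tidy disaggregation
#' @export
tidy.disaggregation <- function(x, ...) {
  tibble(node_id = x$report$removal_set[[1]])
}

#' @export
print.disaggregation <- function(x, ...) {
  r <- x$report
  cat(sprintf("<disaggregation of '%s'> removed %d node(s)\n", r$target,
              length(r$removal_set[[1]])))
  cat(sprintf("  nodes %d -> %d (%d isolated), edges %d -> %d, components %d -> %d\n",
              r$nodes_before, r$nodes_after, r$isolated_after,
              r$edges_before, r$edges_after, r$components_before,
              r$components_after))
  if (!is.na(r$mean_centroid_before)) {
    cat(sprintf("  largest-component mean centroid %.3f -> %.3f, diameter %d -> %d\n",
                r$mean_centroid_before, r$mean_centroid_after,
                r$diameter_before, r$diameter_after))
  }
  invisible(x)
}

#' Extract the connected component of a seed node
#'
#' @param net a [bio_network()].
#' @param seed_node a node id.
#' @return The induced subgraph on the seed's component, as a
#'   [bio_network()].
#' @export
subnetwork_extract <- function(net, seed_node) {
  stopifnot(inherits(net, "bio_network"))
  if (!seed_node %in% igraph::V(net)$name) abort("node not present in network")
  comp <- igraph::components(net)
  idx <- which(comp$membership == comp$membership[[seed_node]])
  sub <- igraph::induced_subgraph(net, idx)
  class(sub) <- class(net)
  sub
}
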