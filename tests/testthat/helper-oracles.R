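# Brute-force oracles, independent of the package internals (and of
# igraph's path algorithms): distances by matrix powers, betweenness by
# exhaustive DFS enumeration of shortest paths.  Only usable on small
# graphs.

adj_matrix <- function(net) {
  ids <- sort(igraph::V(net)$name)
  n <- length(ids)
  A <- matrix(0L, n, n, dimnames = list(ids, ids))
  ee <- network_edges(net)
  for (i in seq_len(nrow(ee))) {
    A[ee$from[i], ee$to[i]] <- 1L
    A[ee$to[i], ee$from[i]] <- 1L
  }
  A
}

oracle_distances <- function(net) {
  A <- adj_matrix(net)
  n <- nrow(A)
  d <- matrix(Inf, n, n, dimnames = dimnames(A))
  diag(d) <- 0
  M <- diag(n)
  for (k in seq_len(n)) {
    M <- M %*% A
    d[M > 0 & is.infinite(d)] <- k
  }
  d
}

# all shortest paths s -> t by depth-first enumeration up to the known
# shortest length
enumerate_shortest_paths <- function(A, s, t, len) {
  paths <- list()
  walk <- function(v, path) {
    if (length(path) - 1 > len) return()
    if (v == t) {
      if (length(path) - 1 == len) paths[[length(paths) + 1]] <<- path
      return()
    }
    for (w in which(A[v, ] > 0)) {
      if (!w %in% path) walk(w, c(path, w))
    }
  }
  walk(s, s)
  paths
}

oracle_betweenness_raw <- function(net) {
  A <- adj_matrix(net)
  d <- oracle_distances(net)
  n <- nrow(A)
  btw <- setNames(numeric(n), rownames(A))
  for (s in seq_len(n - 1)) for (t in (s + 1):n) {
    if (!is.finite(d[s, t])) next
    paths <- enumerate_shortest_paths(A, s, t, d[s, t])
    sigma <- length(paths)
    inner <- unlist(lapply(paths, function(p) p[-c(1, length(p))]))
    if (length(inner)) {
      through <- table(inner)
      idx <- as.integer(names(through))
      btw[idx] <- btw[idx] + as.numeric(through) / sigma
    }
  }
  btw
}

oracle_tn <- function(net) {
  A <- adj_matrix(net)
  ids <- rownames(A)
  vapply(seq_along(ids), function(i) {
    k <- sum(A[i, ])
    if (k < 2) return(0)
    J <- c()
    for (j in seq_along(ids)) {
      if (j == i) next
      shared <- sum(A[i, ] & A[j, ])
      if (shared >= 1) J <- c(J, shared + A[i, j])
    }
    if (!length(J)) return(0)
    mean(J) / k
  }, numeric(1)) |> setNames(ids)
}

oracle_radiality <- function(net, normalized = TRUE) {
  d <- oracle_distances(net)
  ids <- rownames(d)
  out <- setNames(numeric(length(ids)), ids)
  seen <- character()
  for (v in ids) {
    comp <- ids[is.finite(d[v, ])]
    if (length(comp) < 2) next
    diam <- max(d[comp, comp])
    val <- sum(diam + 1 - d[v, setdiff(comp, v)]) / (length(comp) - 1)
    out[v] <- if (normalized) val / diam else val
  }
  out
}

oracle_centroid <- function(net) {
  d <- oracle_distances(net)
  ids <- rownames(d)
  out <- setNames(numeric(length(ids)), ids)
  for (v in ids) {
    comp <- ids[is.finite(d[v, ])]
    if (length(comp) < 2) next
    f <- vapply(setdiff(comp, v), function(w) {
      gvw <- sum(d[comp, v] < d[comp, w])
      gwv <- sum(d[comp, w] < d[comp, v])
      gvw - gwv
    }, numeric(1))
    out[v] <- min(f)
  }
  out
}

# random graph on n nodes, edge probability p, as a bio_network;
# optionally rejection-sampled to be connected
random_graph <- function(n, p = 0.4, connected = FALSE) {
  ids <- sprintf("v%02d", seq_len(n))
  pairs <- t(utils::combn(ids, 2))
  repeat {
    keep <- stats::runif(nrow(pairs)) < p
    net <- bio_network(
      tibble::tibble(id = ids, kind = "gene", label = ids),
      tibble::tibble(from = pairs[keep, 1], to = pairs[keep, 2])
    )
    if (!connected || igraph::is_connected(net)) return(net)
  }
}
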