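#' Read and write networks in standard exchange formats
#'
#' Three formats are supported:
#'
#' * **SIF** (`node<TAB>relation<TAB>node`, one edge per line; a line with
#'   a single field declares an isolated node).  SIF carries no node
#'   attributes, so the node kind is encoded as an id prefix
#'   (`disease:OMIM:...`); labels are not representable and come back
#'   equal to the id.
#' * **GraphML**, via igraph, with vertex attributes `kind` and `label`
#'   and the scheme as a graph attribute -- lossless.
#' * **edge CSV** (`from,to,relation`), with the node attribute table
#'   (`id,kind,label`) written alongside as `<path>.nodes.csv` -- lossless
#'   when both files are present.
#'
#' `write_network()` followed by `read_network()` restores nodes, edges
#' and kinds in every format, and labels in every format except SIF.
#'
#' @param net a [bio_network()].
#' @param path file path.
#' @param format `"sif"`, `"graphml"` or `"edge_csv"` (guessed from the
#'   file extension when omitted).
#' @return `read_network()` a [bio_network()]; `write_network()` the path,
#'   invisibly.
#' @name network_io
NULL

guess_format <- function(path, format) {
  if (!is.null(format)) return(format)
  switch(tolower(tools::file_ext(path)),
         sif = "sif", graphml = "graphml", xml = "graphml", csv = "edge_csv",
         abort(sprintf("cannot guess network format from '%s'", path)))
}

#' @rdname network_io
#' @export
write_network <- function(net, path, format = NULL) {
  stopifnot(inherits(net, "bio_network"))
  format <- match.arg(guess_format(path, format),
                      c("sif", "graphml", "edge_csv"))
  nodes <- network_nodes(net)
  edges <- network_edges(net)
  relation <- scheme_relation[[igraph::graph_attr(net, "scheme") %||% "custom"]] %||%
    "link"
  if (format == "sif") {
    kind_of <- setNames(nodes$kind, nodes$id)
    lines <- sprintf("%s\t%s\t%s",
                     paste0(kind_of[edges$from], ":", edges$from), relation,
                     paste0(kind_of[edges$to], ":", edges$to))
    isolated <- nodes$id[nodes$degree == 0]
    lines <- c(lines, paste0(kind_of[isolated], ":", isolated))
    writeLines(lines, path)
  } else if (format == "graphml") {
    igraph::write_graph(net, path, format = "graphml")
  } else {
    readr::write_csv(tibble(from = edges$from, to = edges$to,
                            relation = relation), path)
    readr::write_csv(select(nodes, "id", "kind", "label"),
                     paste0(path, ".nodes.csv"))
  }
  invisible(path)
}

#' @rdname network_io
#' @param scheme scheme tag to stamp on the network read from SIF or edge
#'   CSV (GraphML carries its own).
#' @export
read_network <- function(path, format = NULL, scheme = "custom") {
  if (!file.exists(path)) abort(sprintf("file '%s' does not exist", path))
  format <- match.arg(guess_format(path, format),
                      c("sif", "graphml", "edge_csv"))
  if (format == "sif") {
    read_sif(path, scheme = scheme)
  } else if (format == "graphml") {
    g <- igraph::read_graph(path, format = "graphml")
    attrs <- igraph::vertex_attr_names(g)
    if (!"kind" %in% attrs) {
      warn("GraphML file has no 'kind' attribute; nodes set to kind 'unknown'")
      igraph::V(g)$kind <- "unknown"
    }
    if (!"label" %in% attrs) igraph::V(g)$label <- igraph::V(g)$name
    bio_network(
      tibble(id = igraph::V(g)$name, kind = igraph::V(g)$kind,
             label = igraph::V(g)$label),
      {
        e <- igraph::as_edgelist(g)
        tibble(from = e[, 1], to = e[, 2])
      },
      scheme = igraph::graph_attr(g, "scheme") %||% scheme
    )
  } else {
    edges <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                             progress = FALSE)
    if (!all(c("from", "to") %in% names(edges))) {
      abort(sprintf("'%s' lacks from/to columns", path),
            class = "retinet_parse_error")
    }
    nodes_path <- paste0(path, ".nodes.csv")
    if (file.exists(nodes_path)) {
      nodes <- readr::read_csv(nodes_path,
                               col_types = readr::cols(.default = "c"),
                               progress = FALSE)
    } else {
      warn("no node attribute table found; nodes set to kind 'unknown'")
      ids <- sort(unique(c(edges$from, edges$to)))
      nodes <- tibble(id = ids, kind = "unknown", label = ids)
    }
    bio_network(nodes, edges, scheme = scheme)
  }
}

split_sif_token <- function(token) {
  kind <- sub(":.*$", "", token)
  if (kind %in% node_kinds && kind != token) {
    c(kind, sub("^[^:]+:", "", token))
  } else {
    c("unknown", token)
  }
}

read_sif <- function(path, scheme = "custom") {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t")
  bad <- which(!lengths(parts) %in% c(1L, 3L))
  if (length(bad)) {
    abort(sprintf("malformed SIF line %d in '%s': expected 1 or 3 fields",
                  bad[1], path), class = "retinet_parse_error")
  }
  tokens <- unique(unlist(lapply(parts, function(p) p[c(1, length(p))])))
  km <- vapply(tokens, split_sif_token, character(2))
  if (any(km[1, ] == "unknown")) {
    warn("SIF node(s) without a kind prefix read as kind 'unknown'")
  }
  nodes <- tibble(id = km[2, ], kind = km[1, ], label = km[2, ])
  epart <- parts[lengths(parts) == 3L]
  edges <- if (length(epart)) {
    tibble(from = vapply(epart, function(p) split_sif_token(p[1])[2], ""),
           to = vapply(epart, function(p) split_sif_token(p[3])[2], ""))
  } else tibble(from = character(), to = character())
  bio_network(distinct(nodes), edges, scheme = scheme)
}

#' Write a centrality table as CSV
#'
#' @param records a tibble from [centrality_table()].
#' @param path output path.
#' @param decimal_mark `"."` (default) or `","` to reproduce the
#'   comma-decimal style of some published tables (fields are then
#'   `;`-separated).
#' @return The path, invisibly.
#' @export
write_centrality_csv <- function(records, path, decimal_mark = ".") {
  if (decimal_mark == ",") {
    readr::write_csv2(records, path)
  } else {
    readr::write_csv(records, path)
  }
  invisible(path)
}
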