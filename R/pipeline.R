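#' Pipeline run configuration
#'
#' Collects every knob of the analysis pipeline in one serializable
#' object.  Exactly one input source is used: a directory of the seven
#' database tables (`db_dir`) or a previously exported network file
#' (`network_path`); the `simulate` step needs neither.
#'
#' @param db_dir directory containing the seven `<table>.csv` files.
#' @param network_path path to a network file (SIF / GraphML / edge CSV).
#' @param scheme network scheme to build from the database.
#' @param scheme_b optional second scheme; the `hubs` step then also
#'   ranks that network and writes the top-`k` label overlap.
#' @param delim,decimal_mark CSV dialect for reading tables and writing
#'   reports.
#' @param strict error on unresolvable foreign keys instead of dropping.
#' @param include_isolates keep edgeless entities when building.
#' @param top_k rows kept by the `hubs` step.
#' @param order_by ranking measure for the `hubs` step.
#' @param hub_rule,hub_value hub threshold rule for [classify_nodes()].
#' @param twin_rule,include_neighbors,drop_isolates disaggregation
#'   options (see [disaggregate()]).
#' @param target node id for the `disaggregate` step.
#' @param drop_node optional node id dropped in a power-law refit.
#' @param synth named list of [synth_params()] overrides for `simulate`.
#' @param seed seed for `simulate`.
#' @param out_dir output directory (created when missing).
#' @param verbosity 0 silences log lines (written to standard error).
#' @return A list of class `run_config`.
#' @export
run_config <- function(db_dir = NULL, network_path = NULL,
                       scheme = "disease_gene", scheme_b = NULL,
                       delim = ",", decimal_mark = ".", strict = FALSE,
                       include_isolates = FALSE, top_k = 10,
                       order_by = "radiality", hub_rule = "mean_sd",
                       hub_value = 2, twin_rule = "identical_neighborhood",
                       include_neighbors = TRUE, drop_isolates = FALSE,
                       target = NULL, drop_node = NULL, synth = list(),
                       seed = 1, out_dir = "retinet-out", verbosity = 1) {
  cfg <- as.list(environment())
  structure(cfg, class = "run_config")
}

#' @rdname run_config
#' @param path YAML file path.
#' @export
write_run_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "run_config"))
  yaml::write_yaml(cfg[!vapply(cfg, is.null, logical(1))], path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  do.call(run_config, yaml::read_yaml(path))
}

#' @rdname run_config
#' @param cfg a `run_config`.
#' @param x,... object and ignored dots (print method).
#' @export
print.run_config <- function(x, ...) {
  cat("<run_config>\n")
  for (nm in names(x)) {
    if (!is.null(x[[nm]]) && !identical(x[[nm]], list())) {
      cat(sprintf("  %s: %s\n", nm, paste(unlist(x[[nm]]), collapse = ", ")))
    }
  }
  invisible(x)
}

vlog <- function(cfg, fmt, ...) {
  if ((cfg$verbosity %||% 1) >= 1) message("INFO: ", sprintf(fmt, ...))
}

cfg_db <- function(cfg) {
  if (is.null(cfg$db_dir)) abort("this step needs 'db_dir' in the config")
  read_relational_db(cfg$db_dir, delim = cfg$delim,
                     decimal_mark = cfg$decimal_mark, strict = cfg$strict)
}

cfg_network <- function(cfg, scheme = cfg$scheme) {
  if (!is.null(cfg$network_path)) {
    if (!is.null(cfg$db_dir)) {
      abort("config must give exactly one of db_dir / network_path")
    }
    read_network(cfg$network_path, scheme = scheme)
  } else {
    build_network(cfg_db(cfg), scheme = scheme,
                  include_isolates = cfg$include_isolates)
  }
}

out_path <- function(cfg, ...) {
  if (!dir.exists(cfg$out_dir)) dir.create(cfg$out_dir, recursive = TRUE)
  file.path(cfg$out_dir, ...)
}

report_csv <- function(cfg, df, name) {
  p <- out_path(cfg, name)
  write_centrality_csv(df, p, decimal_mark = cfg$decimal_mark)
  p
}

#' Run one pipeline step end to end
#'
#' Steps: `simulate` (generate a synthetic database and write its seven
#' tables plus a manifest), `build` (project the database onto a scheme
#' and export the network), `analyze` (centrality table, degree-class
#' distributions, summary), `fit_powerlaw` (degree histogram and fit
#' report, with optional one-node-removed refit), `hubs` (top-`k`
#' ranking, scatter coordinates, node classification, and -- when
#' `scheme_b` is set -- the top-table label overlap), and `disaggregate`
#' (removal experiment report and after-network).  Every step logs the
#' under-specified conventions it relies on, and identical configurations
#' produce identical artifact files.
#'
#' @param cfg a [run_config()].
#' @param step the step to run.
#' @return Invisibly, a named list with the computed objects and the
#'   paths of the artifacts written.
#' @export
run_pipeline <- function(cfg, step = c("simulate", "build", "analyze",
                                       "fit_powerlaw", "hubs",
                                       "disaggregate")) {
  stopifnot(inherits(cfg, "run_config"))
  step <- match.arg(step)
  switch(step,
    simulate = {
      params <- do.call(synth_params, c(cfg$synth, list(seed = cfg$seed)))
      db <- generate_db(params)
      dir <- out_path(cfg, "tables")
      paths <- write_relational_db(db, dir, delim = cfg$delim)
      manifest <- out_path(cfg, "manifest.json")
      jsonlite::write_json(
        c(unclass(params), list(generator = "R Mersenne-Twister stream")),
        manifest, auto_unbox = TRUE, digits = NA)
      vlog(cfg, "simulate: wrote %d tables to %s (seed %d)", length(paths),
           dir, params$seed)
      invisible(list(db = db, paths = c(paths, manifest = manifest)))
    },
    build = {
      net <- cfg_network(cfg)
      p_g <- out_path(cfg, paste0(cfg$scheme, ".graphml"))
      p_s <- out_path(cfg, paste0(cfg$scheme, ".sif"))
      write_network(net, p_g, "graphml")
      write_network(net, p_s, "sif")
      p_n <- report_csv(cfg, select(network_nodes(net), "id", "kind", "label"),
                        paste0(cfg$scheme, "_nodes.csv"))
      p_sum <- report_csv(cfg, network_summary(net), "network_summary.csv")
      vlog(cfg, "build: %s with %d nodes / %d edges", cfg$scheme,
           igraph::vcount(net), igraph::ecount(net))
      invisible(list(network = net, paths = c(p_g, p_s, p_n, p_sum)))
    },
    analyze = {
      vlog(cfg, paste("analyze conventions: radiality normalized by component",
                      "diameter; betweenness normalized per component;",
                      "unweighted shortest paths"))
      net <- cfg_network(cfg)
      ct <- centrality_table(net)
      dists <- clustering_connectivity_distributions(net)
      paths <- c(
        report_csv(cfg, ct, "centrality_table.csv"),
        report_csv(cfg, dists$clustering, "clustering_distribution.csv"),
        report_csv(cfg, dists$connectivity, "connectivity_distribution.csv"),
        report_csv(cfg, network_summary(net), "network_summary.csv")
      )
      invisible(list(centrality = ct, distributions = dists, paths = paths))
    },
    fit_powerlaw = {
      vlog(cfg, paste("fit conventions: unweighted least squares on log-log",
                      "binned counts; r-squared on the log scale;",
                      "correlation on the original scale"))
      net <- cfg_network(cfg)
      hist <- degree_distribution_table(net)
      p_h <- report_csv(cfg, hist, "degree_histogram.csv")
      if (!is.null(cfg$drop_node)) {
        rf <- refit_without_node(net, cfg$drop_node)
        rep <- bind_rows(mutate(glance(rf$before), fit = "before"),
                         mutate(glance(rf$after), fit = "after"))
        fit <- rf$before
      } else {
        fit <- fit_power_law(hist)
        rep <- mutate(glance(fit), fit = "full")
      }
      rep <- mutate(rep, scheme = cfg$scheme)
      p_r <- report_csv(cfg, rep, "powerlaw_fit.csv")
      p_j <- out_path(cfg, "powerlaw_fit.json")
      jsonlite::write_json(rep, p_j, auto_unbox = TRUE, digits = NA)
      invisible(list(fit = fit, report = rep, paths = c(p_h, p_r, p_j)))
    },
    hubs = {
      net <- cfg_network(cfg)
      ct <- centrality_table(net)
      top <- rank_nodes(ct, order_by = cfg$order_by, k = cfg$top_k)
      cls <- classify_nodes(net, rule = cfg$hub_rule, value = cfg$hub_value)
      vlog(cfg, "hubs: threshold rule %s, degree threshold %.2f",
           cfg$hub_rule, attr(cls, "hub_threshold"))
      paths <- c(report_csv(cfg, select(top, -"label"), "hub_table.csv"),
                 report_csv(cfg, cls, "node_classes.csv"))
      for (pair in list(c("tn", "radiality"), c("tn", "betweenness"),
                        c("radiality", "betweenness"))) {
        sp <- scatter_points(ct, pair[1], pair[2])
        paths <- c(paths, report_csv(cfg, sp,
                                     sprintf("scatter_%s_vs_%s.csv",
                                             pair[1], pair[2])))
      }
      overlap <- NULL
      if (!is.null(cfg$scheme_b)) {
        db <- cfg_db(cfg)
        net_b <- build_network(db, scheme = cfg$scheme_b,
                               include_isolates = cfg$include_isolates)
        top_b <- rank_nodes(centrality_table(net_b),
                            order_by = cfg$order_by, k = cfg$top_k)
        overlap <- top_overlap(top, top_b, label_map = protein_gene_map(db))
        p_o <- out_path(cfg, "top_overlap.txt")
        writeLines(overlap, p_o)
        paths <- c(paths, p_o)
        vlog(cfg, "hubs: %d shared label(s) between %s and %s top-%d",
             length(overlap), cfg$scheme, cfg$scheme_b, cfg$top_k)
      }
      invisible(list(top = top, classes = cls, overlap = overlap,
                     paths = paths))
    },
    disaggregate = {
      if (is.null(cfg$target)) abort("the disaggregate step needs 'target'")
      net <- cfg_network(cfg)
      dis <- disaggregate(net, cfg$target,
                          include_neighbors = cfg$include_neighbors,
                          twin_rule = cfg$twin_rule,
                          drop_isolates = cfg$drop_isolates)
      rep <- mutate(glance(dis),
                    removal_set = paste(.data$removal_set[[1]],
                                        collapse = ";"))
      p_r <- report_csv(cfg, rep, "disaggregation_report.csv")
      p_j <- out_path(cfg, "disaggregation_report.json")
      jsonlite::write_json(rep, p_j, auto_unbox = TRUE, digits = NA)
      p_a <- out_path(cfg, "after_network.sif")
      write_network(dis$after, p_a, "sif")
      vlog(cfg, "disaggregate '%s': nodes %d -> %d, edges %d -> %d",
           cfg$target, rep$nodes_before, rep$nodes_after, rep$edges_before,
           rep$edges_after)
      invisible(list(result = dis, paths = c(p_r, p_j, p_a)))
    }
  )
}
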