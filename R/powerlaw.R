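#' Degree histogram of a network
#'
#' @param net a [bio_network()].
#' @param kind optionally restrict to nodes of one kind (e.g. `"gene"`
#'   for the gene-side distribution of a bipartite scheme).
#' @return A tibble `degree`, `count` over nodes of degree `>= 1`
#'   (degree-0 nodes are excluded: the log-log fit is undefined for them),
#'   degrees strictly increasing.  A network with no edges yields an empty
#'   histogram.
#' @export
degree_distribution_table <- function(net, kind = NULL) {
  stopifnot(inherits(net, "bio_network"))
  deg <- igraph::degree(net)
  if (!is.null(kind)) deg <- deg[igraph::V(net)$kind %in% kind]
  deg <- deg[deg >= 1]
  if (!length(deg)) return(tibble(degree = integer(), count = integer()))
  tab <- table(deg)
  tibble(degree = as.integer(names(tab)), count = as.integer(tab)) |>
    arrange(.data$degree)
}

#' Fit a power law to a degree histogram
#'
#' Fits `y = a * k^b` by unweighted least squares on the log-log pairs
#' `(log k, log y)` -- the convention of network-analyzer style degree
#' fits; no truncation of the degree range is applied.  Two association
#' statistics are reported: `r_squared`, the coefficient of determination
#' of the log-log regression, and `correlation`, the Pearson correlation
#' between observed counts and fitted `a * k^b` on the original scale.
#' The two deliberately differ (the original-scale correlation weights the
#' large-count head much more heavily).
#'
#' A histogram whose counts are all equal has zero variance on the log
#' scale: the fit degenerates to `b = 0`, `a = y`, and both statistics are
#' reported as 1 with `zero_variance = TRUE`.
#'
#' @param hist a data frame with columns `degree` and `count` (e.g. from
#'   [degree_distribution_table()]), at least two distinct degrees, all
#'   counts positive.
#' @return An object of class `power_law_fit` with elements `a`, `b`,
#'   `correlation`, `r_squared`, `n_points`, `zero_variance`, and `data`
#'   (the histogram with a `fitted` column).  Supports [tidy()],
#'   [glance()], [autoplot()] and `print()`.
#' @export
fit_power_law <- function(hist) {
  hist <- as_tibble(hist)
  stopifnot(all(c("degree", "count") %in% names(hist)))
  hist <- arrange(hist, .data$degree)
  if (nrow(hist) < 2) {
    abort("power-law fit needs at least two distinct degrees",
          class = "retinet_fit_error")
  }
  if (any(hist$count <= 0) || any(hist$degree <= 0)) {
    abort("degrees and counts must be positive", class = "retinet_fit_error")
  }
  lk <- log(hist$degree)
  ly <- log(hist$count)
  zero_var <- isTRUE(all.equal(var(ly), 0)) || var(ly) == 0
  if (zero_var) {
    a <- exp(mean(ly))
    b <- 0
    r2 <- 1
    correlation <- 1
  } else {
    fit <- lm(ly ~ lk)
    b <- unname(coef(fit)[2])
    a <- exp(unname(coef(fit)[1]))
    # coefficient of determination computed directly (summary.lm warns on
    # numerically exact fits)
    r2 <- 1 - sum(fit$residuals^2) / sum((ly - mean(ly))^2)
    fitted <- a * hist$degree^b
    correlation <- if (sd(fitted) == 0) NA_real_ else cor(hist$count, fitted)
  }
  structure(
    list(a = a, b = b, correlation = correlation, r_squared = r2,
         n_points = nrow(hist), zero_variance = zero_var,
         data = mutate(hist, fitted = a * .data$degree^b)),
    class = "power_law_fit"
  )
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat(sprintf("<power_law_fit> y = %.4g * k^%.4g on %d degree classes\n",
              x$a, x$b, x$n_points))
  cat(sprintf("  r-squared (log-log) = %.4f, correlation (original scale) = %.4f%s\n",
              x$r_squared, x$correlation,
              if (x$zero_variance) " [zero-variance histogram]" else ""))
  invisible(x)
}

#' @method tidy power_law_fit
#' @export
tidy.power_law_fit <- function(x, ...) {
  tibble(term = c("a", "b"), estimate = c(x$a, x$b))
}

#' @method glance power_law_fit
#' @export
glance.power_law_fit <- function(x, ...) {
  tibble(a = x$a, b = x$b, correlation = x$correlation,
         r_squared = x$r_squared, n_points = x$n_points,
         zero_variance = x$zero_variance)
}

#' Refit the degree distribution after removing one node
#'
#' Recomputes the degree histogram with a single node (typically a
#' suspected outlier) deleted from the network and refits the power law,
#' returning both fits so the change in goodness of fit is directly
#' comparable.
#'
#' @param net a [bio_network()].
#' @param node_id id of the node to remove.
#' @return A list with elements `before` and `after`, both
#'   `power_law_fit` objects, and `node_id`.
#' @export
refit_without_node <- function(net, node_id) {
  stopifnot(inherits(net, "bio_network"))
  if (!node_id %in% igraph::V(net)$name) abort("node not present in network")
  before <- fit_power_law(degree_distribution_table(net))
  reduced <- igraph::delete_vertices(net, node_id)
  class(reduced) <- class(net)
  after <- fit_power_law(degree_distribution_table(reduced))
  list(before = before, after = after, node_id = node_id)
}

#' @describeIn fit_power_law plot the histogram and fitted line on
#'   log-log axes.
#' @param object,... a `power_law_fit` and ignored dots (autoplot method).
#' @method autoplot power_law_fit
#' @export
autoplot.power_law_fit <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$degree)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$count)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "blue") +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(
      x = "node degree", y = "number of nodes",
      title = sprintf("y = %.3g k^%.3g  (r-squared = %.3f)",
                      object$a, object$b, object$r_squared)
    ) +
    ggplot2::theme_minimal()
}
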