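# Topology statistic bundle: degrees, clustering, path statistics, closeness
# centrality, and log-log least-squares power-law fits of the degree and
# clustering spectra. All statistics are computed on the simple view
# (self-loops dropped, parallel edges collapsed); degree means the number of
# *distinct* neighbors.

#' Degree sequence (distinct-neighbor counts)
#'
#' @param net A `signaling_network`.
#' @return Named integer vector, node id -> number of distinct neighbors in
#'   the simple view. Satisfies `sum(degree) == 2 * n_edges_simple(net)`.
#' @export
degree_sequence <- function(net) {
  g <- as_igraph(net)
  d <- igraph::degree(g, loops = FALSE)
  stats::setNames(as.integer(d), igraph::V(g)$name)[node_ids(net)]
}

#' Local clustering coefficient
#'
#' The fraction `2 n / (k (k - 1))` of realized links among a node's `k`
#' distinct neighbors, where `n` counts the edges connecting those neighbors
#' to each other. Undefined (`NA`) for nodes of degree < 2, which are
#' excluded from averages by default (see [topology_report()]).
#'
#' @param net A `signaling_network`.
#' @param node A single node id, or `NULL` for all nodes.
#' @return A numeric value, or a named vector over all nodes when
#'   `node = NULL`; `NA` where degree < 2.
#' @export
node_clustering <- function(net, node = NULL) {
  g <- as_igraph(net)
  cc <- igraph::transitivity(g, type = "local", isolates = "NaN")
  cc[is.nan(cc)] <- NA_real_
  cc <- stats::setNames(cc, igraph::V(g)$name)[node_ids(net)]
  if (is.null(node)) return(cc)
  if (!node %in% names(cc)) stop("unknown node id: ", node)
  unname(cc[[node]])
}

#' All-pairs shortest path lengths
#'
#' Breadth-first distances on the simple view; symmetric, zero diagonal,
#' `Inf` between nodes in different components.
#'
#' @param net A `signaling_network`.
#' @return Numeric matrix with node ids as dimnames.
#' @export
shortest_path_lengths <- function(net) {
  g <- as_igraph(net)
  d <- igraph::distances(g, algorithm = "unweighted")
  ids <- node_ids(net)
  d[ids, ids, drop = FALSE]
}

#' Characteristic path length
#'
#' Mean shortest-path distance over unordered *connected* node pairs;
#' unreachable pairs are excluded rather than counted as infinite, matching
#' the convention of the NetworkAnalyzer statistic on networks with more
#' than one component.
#'
#' @param net A `signaling_network`.
#' @return Mean finite distance, or `NA` if no connected pair exists.
#' @export
characteristic_path_length <- function(net) {
  d <- shortest_path_lengths(net)
  v <- d[upper.tri(d)]
  v <- v[is.finite(v)]
  if (!length(v)) return(NA_real_)
  mean(v)
}

#' Network diameter
#'
#' Maximum finite shortest-path distance, i.e. the largest eccentricity
#' within any connected component. An edgeless network has diameter 0.
#'
#' @param net A `signaling_network`.
#' @return Non-negative integer.
#' @export
network_diameter <- function(net) {
  d <- shortest_path_lengths(net)
  v <- d[upper.tri(d)]
  v <- v[is.finite(v)]
  if (!length(v)) return(0L)
  as.integer(max(v))
}

#' Average number of neighbors
#'
#' Mean over all nodes of the distinct-neighbor count (the mean degree of
#' the simple view). On a network whose raw interaction list contains
#' duplicates this is smaller than `2 * n_interactions_raw / n_nodes`.
#'
#' @param net A `signaling_network`.
#' @return Non-negative real.
#' @export
average_neighbors <- function(net) {
  if (n_nodes(net) == 0L) stop("empty network")
  mean(degree_sequence(net))
}

#' Closeness centrality of every node
#'
#' `C_c(n) = 1 / mean(L(n, m))`, the reciprocal of the mean shortest-path
#' length from `n` to the nodes reachable from it (itself excluded).
#' Values lie in `[0, 1]`: 1 for a node adjacent to everything it can
#' reach, and 0 by convention for an isolated node.
#'
#' @param net A `signaling_network`.
#' @return Data frame with columns `node`, `closeness`, `reachable_count`,
#'   in node storage order.
#' @export
closeness_centrality <- function(net) {
  d <- shortest_path_lengths(net)
  ids <- node_ids(net)
  res <- vapply(seq_along(ids), function(i) {
    row <- d[i, -i]
    row <- row[is.finite(row)]
    if (!length(row)) return(c(0, 0))
    c(1 / mean(row), length(row))
  }, numeric(2))
  data.frame(node = ids, closeness = res[1, ],
             reachable_count = as.integer(res[2, ]),
             stringsAsFactors = FALSE)
}

#' Least-squares power-law fit on log-log scale
#'
#' Fits `y = a * x^b` by ordinary least squares of `ln y` on `ln x`:
#' `exponent_b` is the slope, `prefactor_a = exp(intercept)`, `pearson_r`
#' the correlation of the log-log points, and `r_squared = pearson_r^2`.
#' This is the straight-line fit a network analyzer applies to a degree
#' distribution, not a maximum-likelihood tail estimate.
#'
#' @param x,y Positive numeric vectors of equal length. Non-positive pairs
#'   are dropped before fitting.
#' @return A `power_law_fit` object with fields `exponent_b`, `prefactor_a`,
#'   `pearson_r`, `r_squared`, `n_points` and `fitted`. When fewer than two
#'   positive points remain, `fitted` is `FALSE` and the statistics are `NA`.
#' @examples
#' fit_power_law(1:10, 2 * (1:10)^-1.5)  # recovers b = -1.5, a = 2
#' @export
fit_power_law <- function(x, y) {
  keep <- is.finite(x) & is.finite(y) & x > 0 & y > 0
  x <- x[keep]; y <- y[keep]
  unfit <- structure(
    list(exponent_b = NA_real_, prefactor_a = NA_real_,
         pearson_r = NA_real_, r_squared = NA_real_,
         n_points = length(x), fitted = FALSE),
    class = "power_law_fit")
  if (length(x) < 2L) return(unfit)
  lx <- log(x); ly <- log(y)
  if (stats::var(lx) == 0) return(unfit)  # vertical: slope undefined
  fit <- stats::lm.fit(cbind(1, lx), ly)
  b <- unname(fit$coefficients[[2]])
  a <- exp(unname(fit$coefficients[[1]]))
  r <- if (stats::var(ly) == 0) {
    # horizontal line: perfect fit, zero correlation by convention
    0
  } else {
    stats::cor(lx, ly)
  }
  structure(
    list(exponent_b = b, prefactor_a = a, pearson_r = r, r_squared = r^2,
         n_points = length(x), fitted = TRUE),
    class = "power_law_fit")
}

#' @export
print.power_law_fit <- function(x, ...) {
  if (!x$fitted) {
    cat(sprintf("<power_law_fit> not fitted (%d usable point(s))\n",
                x$n_points))
  } else {
    cat(sprintf(
      "<power_law_fit> y = %.4g * x^%.4g  (r = %.3f, R^2 = %.3f, %d points)\n",
      x$prefactor_a, x$exponent_b, x$pearson_r, x$r_squared, x$n_points))
  }
  invisible(x)
}

#' Power-law fit of the degree distribution
#'
#' Builds the un-binned frequency spectrum (degree `k`, number of nodes of
#' degree `k`) for `k >= 1`, skipping zero-count degrees, then applies
#' [fit_power_law()]. A scale-free network yields a negative exponent with
#' high `R^2`; a degenerate spectrum (fewer than two distinct positive
#' degrees) yields `fitted = FALSE`.
#'
#' @param net A `signaling_network`.
#' @return A `power_law_fit`.
#' @export
degree_distribution_fit <- function(net) {
  deg <- degree_sequence(net)
  deg <- deg[deg >= 1L]
  if (!length(deg)) return(fit_power_law(numeric(0), numeric(0)))
  tab <- table(deg)
  k <- as.numeric(names(tab))
  cnt <- as.numeric(tab)
  fit_power_law(k, cnt)
}

#' Power-law fit of the clustering-coefficient spectrum
#'
#' Builds points (degree `k`, mean local clustering of degree-`k` nodes)
#' for `k >= 2` with positive mean, then applies [fit_power_law()]. For a
#' hierarchically modular network the spectrum decays with `k`; a weak fit
#' (low `r`, `R^2`) is a legitimate, reported outcome, not an error.
#'
#' @param net A `signaling_network`.
#' @return A `power_law_fit`.
#' @export
clustering_distribution_fit <- function(net) {
  deg <- degree_sequence(net)
  cc <- node_clustering(net)
  keep <- deg >= 2L & !is.na(cc)
  if (!any(keep)) return(fit_power_law(numeric(0), numeric(0)))
  spectrum <- tapply(cc[keep], deg[keep], mean)
  k <- as.numeric(names(spectrum))
  m <- as.numeric(spectrum)
  pos <- m > 0
  fit_power_law(k[pos], m[pos])
}

#' Full topology report
#'
#' Assembles the statistic bundle reported for a signaling network: node,
#' simple-edge and raw interaction counts, network-average clustering
#' coefficient, diameter, mean neighbor count, characteristic path length,
#' and the power-law fits of the degree and clustering spectra. Every field
#' equals the corresponding individually-called operation; the report is
#' deterministic for a given network.
#'
#' @param net A `signaling_network`.
#' @param count_degree_lt2_as_zero Convention switch for the clustering
#'   average: the coefficient is undefined at degree < 2, and by default
#'   such nodes are excluded from the mean; set `TRUE` to count them as 0
#'   instead (both conventions exist in common network tools).
#' @return An object of class `topology_report` (a list with fields
#'   `n_nodes`, `n_edges_simple`, `n_interactions_raw`, `avg_clustering`,
#'   `diameter`, `avg_neighbors`, `char_path_length`, `degree_fit`,
#'   `clustering_fit`).
#' @export
topology_report <- function(net, count_degree_lt2_as_zero = FALSE) {
  cc <- node_clustering(net)
  if (count_degree_lt2_as_zero) cc[is.na(cc)] <- 0
  avg_cc <- if (all(is.na(cc))) NA_real_ else mean(cc, na.rm = TRUE)
  structure(
    list(
      n_nodes = n_nodes(net),
      n_edges_simple = n_edges_simple(net),
      n_interactions_raw = n_interactions_raw(net),
      avg_clustering = avg_cc,
      diameter = network_diameter(net),
      avg_neighbors = if (n_nodes(net)) average_neighbors(net) else NA_real_,
      char_path_length = characteristic_path_length(net),
      degree_fit = degree_distribution_fit(net),
      clustering_fit = clustering_distribution_fit(net)
    ),
    class = "topology_report")
}

#' @export
print.topology_report <- function(x, ...) {
  cat("<topology_report>\n")
  cat(sprintf("  nodes: %d   simple edges: %d   raw interactions: %d\n",
              x$n_nodes, x$n_edges_simple, x$n_interactions_raw))
  cat(sprintf("  clustering coefficient: %s\n", format(x$avg_clustering)))
  cat(sprintf("  diameter: %d   char. path length: %s   avg neighbors: %s\n",
              x$diameter, format(x$char_path_length),
              format(x$avg_neighbors)))
  cat("  degree fit: "); print(x$degree_fit)
  cat("  clustering fit: "); print(x$clustering_fit)
  invisible(x)
}
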