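#' Summary statistics of a network
#'
#' Computes the structural covariates used when relating networks to the
#' structural diversity index: degree moments and the two degree-heterogeneity
#' conventions, the Wiener index, edge density, and two clustering
#' conventions.
#'
#' Degree heterogeneity comes in two flavours: `kappa_moment_ratio`
#' (\eqn{\langle k^2\rangle/\langle k\rangle}, the moment-ratio convention
#' used for descriptive statistics and regressions) and `kappa_normalized`
#' (\eqn{\langle k^2\rangle/\langle k\rangle^2}, the dimensionless version
#' entering the heterogeneity bound; equals 1 exactly on regular graphs).
#' Clustering is reported both as global transitivity (`clustering_global`,
#' the default for regressions) and as the mean of the local coefficients
#' over vertices of degree at least 2 (`clustering_mean_local`).
#'
#' @param g an undirected igraph.
#' @return an object of class `network_stats`: a list with fields `size`,
#'   `n_edges`, `mean_degree`, `second_moment`, `max_degree`,
#'   `kappa_moment_ratio`, `kappa_normalized`, `wiener_index`,
#'   `mean_distance`, `edge_density`, `clustering_global`,
#'   `clustering_mean_local`, `is_bipartite`, `is_connected`.
#'   `wiener_index` is `Inf` for disconnected graphs (sum of shortest-path
#'   lengths over unordered pairs otherwise).
#' @export
#' @examples
#' st <- network_statistics(graph_complete(3))
#' st$wiener_index # 3
network_statistics <- function(g) {
  degs <- igraph::degree(g)
  n <- igraph::vcount(g)
  connected <- igraph::is_connected(g)
  if (connected) {
    wiener <- sum(igraph::distances(g)) / 2
  } else {
    wiener <- Inf
  }
  loc <- igraph::transitivity(g, type = "local")
  loc <- loc[!is.nan(loc)]
  glob <- igraph::transitivity(g, type = "global")
  structure(list(
    size = n,
    n_edges = igraph::ecount(g),
    mean_degree = mean(degs),
    second_moment = mean(degs^2),
    max_degree = max(degs),
    kappa_moment_ratio = mean(degs^2) / mean(degs),
    kappa_normalized = mean(degs^2) / mean(degs)^2,
    wiener_index = wiener,
    mean_distance = wiener / (n * (n - 1) / 2),
    edge_density = 2 * igraph::ecount(g) / (n * (n - 1)),
    clustering_global = if (is.nan(glob)) 0 else glob,
    clustering_mean_local = if (length(loc) == 0) 0 else mean(loc),
    is_bipartite = is_two_colourable(g),
    is_connected = connected
  ), class = "network_stats")
}

#' @export
print.network_stats <- function(x, ...) {
  cat("Network statistics\n")
  cat(sprintf("  size %d, edges %d, <k> %.3f, <k^2> %.3f, Dmax %d\n",
              x$size, x$n_edges, x$mean_degree, x$second_moment,
              x$max_degree))
  cat(sprintf("  kappa <k^2>/<k> %.4f, normalized <k^2>/<k>^2 %.4f\n",
              x$kappa_moment_ratio, x$kappa_normalized))
  cat(sprintf("  Wiener %.0f, edge density %.4f\n", x$wiener_index,
              x$edge_density))
  cat(sprintf("  clustering: global %.4f, mean local %.4f\n",
              x$clustering_global, x$clustering_mean_local))
  cat(sprintf("  connected %s, bipartite %s\n", x$is_connected,
              x$is_bipartite))
  invisible(x)
}

#' Spectral information of the random-walk operator
#'
#' The transition matrix of the simple random walk is `P(i, j) = 1/deg(i)`
#' for neighbours `j`. Its spectrum is computed through the symmetrized
#' operator \eqn{D^{-1/2} A D^{-1/2}} (same eigenvalues, numerically stable).
#' `lambda2` is the second-largest algebraic eigenvalue; `1/(1 - lambda2)`
#' is the relaxation factor entering the meeting-time upper bound.
#'
#' Dense eigensolve; refused above `max_size` vertices.
#'
#' @param g a connected undirected igraph.
#' @param max_size largest graph accepted (default 5000).
#' @return a list with `lambda2` and `relaxation_factor`.
#' @export
#' @examples
#' spectral_info(graph_complete(4))$lambda2 # -1/3
spectral_info <- function(g, max_size = 5000) {
  assert_connected(g, "spectral_info()")
  n <- igraph::vcount(g)
  if (n > max_size) {
    stop("graph too large for dense eigensolve (", n, " > ", max_size,
         " vertices); sparse/approximate spectral methods are out of scope",
         call. = FALSE)
  }
  A <- igraph::as_adjacency_matrix(g, sparse = FALSE)
  dinv <- 1 / sqrt(igraph::degree(g))
  N <- A * outer(dinv, dinv)
  ev <- sort(eigen(N, symmetric = TRUE, only.values = TRUE)$values,
             decreasing = TRUE)
  lambda2 <- ev[2]
  list(lambda2 = lambda2, relaxation_factor = 1 / (1 - lambda2))
}
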