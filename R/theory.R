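bound_report <- function(family, value, kind, inputs) {
  structure(list(graph_family = family, value = value, kind = kind,
                 inputs = inputs), class = "bound_report")
}

#' @export
print.bound_report <- function(x, ...) {
  cat(sprintf("Bound report [%s, %s]: value = %.6g\n", x$graph_family,
              x$kind, x$value))
  if (length(x$inputs) > 0) {
    cat("  inputs:", paste(names(x$inputs), unlist(x$inputs), sep = " = ",
                           collapse = ", "), "\n")
  }
  invisible(x)
}

#' Predicted long-run diversity from the structural diversity index
#'
#' The master relation between network structure and long-run Simpson
#' diversity under neutral imitation-innovation dynamics:
#' \deqn{D_\infty \approx 1 - e^{-2 \alpha \Delta(G)},}
#' where `alpha` is the per-capita innovation rate \eqn{r |V|}. For larger
#' innovation probabilities the small-`r` linearization `2r` can be replaced
#' by the exact two-walk halting rate `q(r) = 2r - r^2`: set `exact_q = TRUE`
#' and supply `r` and `n_vertices`, giving
#' `1 - exp(-q(r) * delta * n_vertices)`.
#'
#' @param delta structural diversity index value (>= 0).
#' @param alpha per-capita innovation rate (>= 0).
#' @param exact_q use `q(r) = 2r - r^2` instead of `2r`.
#' @param r innovation probability (required when `exact_q = TRUE`).
#' @param n_vertices network size (required when `exact_q = TRUE`).
#' @return predicted diversity in `[0, 1)`.
#' @export
#' @examples
#' predicted_diversity(1, 1) # 1 - exp(-2) = 0.8647
predicted_diversity <- function(delta, alpha = NULL, exact_q = FALSE,
                                r = NULL, n_vertices = NULL) {
  if (any(delta < 0)) stop("`delta` must be non-negative", call. = FALSE)
  if (exact_q) {
    if (is.null(r) || is.null(n_vertices)) {
      stop("`exact_q = TRUE` needs `r` and `n_vertices`", call. = FALSE)
    }
    q <- 2 * r - r^2
    return(1 - exp(-q * delta * n_vertices))
  }
  if (is.null(alpha) || any(!is.finite(alpha)) || any(alpha < 0)) {
    stop("`alpha` must be non-negative", call. = FALSE)
  }
  1 - exp(-2 * alpha * delta)
}

#' Classify a network as diversity amplifier or suppressor
#'
#' The benchmark is the complete graph, whose index is 1 independent of
#' size. Networks with index below `1 - tolerance` structurally suppress
#' diversity, above `1 + tolerance` amplify it, in between they are
#' neutral. When the index is a Monte-Carlo estimate, a tolerance of about
#' 3 standard errors is sensible.
#'
#' @param delta index value (>= 0), point estimate.
#' @param tolerance half-width of the neutral band around 1 (default 0).
#' @return `"suppressor"`, `"amplifier"` or `"neutral"`.
#' @export
classify_network <- function(delta, tolerance = 0) {
  if (any(delta < 0)) stop("`delta` must be non-negative", call. = FALSE)
  ifelse(delta < 1 - tolerance, "suppressor",
         ifelse(delta > 1 + tolerance, "amplifier", "neutral"))
}

#' Structural diversity index of the complete graph
#'
#' On the complete graph two walkers at distinct vertices meet in any step
#' with a probability close to `1/n`, making the meeting time geometric and
#' the index 1 independent of size (the benchmark convention). The exact
#' pair-chain value accounts for the uniform (possibly coincident) starts
#' and the excluded self-moves: \eqn{(1 - 1/n)(n-1)^2 / ((n-2) n)}, which
#' tends to 1 as `n` grows.
#'
#' @param n number of vertices (>= 3; the 2-vertex complete graph is
#'   bipartite and has no finite meeting time).
#' @param exact return the exact pair-chain value instead of the benchmark 1.
#' @return a `bound_report` object with `kind = "exact"`.
#' @export
complete_graph_index <- function(n, exact = FALSE) {
  n <- assert_count(n, "n", min = 3)
  value <- if (exact) (1 - 1 / n) * (n - 1)^2 / ((n - 2) * n) else 1
  bound_report("complete", value, "exact", list(n = n, exact = exact))
}

#' Scale-free index bound
#'
#' Upper bound on the structural diversity index of a power-law network with
#' exponent `gamma`, obtained from the degree-moment bound with the moments
#' evaluated for a power-law degree distribution with natural cutoff:
#' piecewise `1` for `gamma >= 3`, `n^(-(3 - gamma)/(gamma - 1))` for
#' `2 < gamma < 3`, and `n^-1` for `gamma <= 2`. Continuous and increasing
#' in `gamma` on (2, 3): heavier tails suppress diversity more.
#'
#' @param n network size.
#' @param gamma power-law exponent (> 1).
#' @return a `bound_report` object with `kind = "upper_bound"`.
#' @export
#' @examples
#' scale_free_bound(1000, 2.5)$value # 0.1
scale_free_bound <- function(n, gamma) {
  n <- assert_count(n, "n", min = 2)
  if (!is.finite(gamma) || gamma <= 1) stop("`gamma` must be > 1", call. = FALSE)
  value <- if (gamma >= 3) 1
           else if (gamma > 2) n^(-(3 - gamma) / (gamma - 1))
           else 1 / n
  bound_report("scale_free", value, "upper_bound",
               list(n = n, gamma = gamma))
}

#' Watts-Strogatz index approximation
#'
#' Empirical closed form for the index of a Watts-Strogatz network with
#' rewiring probability `s` and mean degree `k`:
#' \deqn{\Delta(W_s) \approx (s + 1/k) / (2s + 1/n).}
#' Decreasing in `s`; it exceeds 1 exactly when `s <= 1/k - 1/n`, so the
#' amplifier regime is the small-`s` (few long-range ties) regime.
#'
#' @param n network size.
#' @param k mean degree (>= 1).
#' @param s rewiring probability in `[0, 1]`.
#' @return a `bound_report` object with `kind = "approximation"`.
#' @export
#' @examples
#' ws_index_approximation(1000, 6, 0.01)$value # about 8.41
ws_index_approximation <- function(n, k, s) {
  n <- assert_count(n, "n", min = 2)
  if (!is.finite(k) || k < 1) stop("`k` must be >= 1", call. = FALSE)
  if (!is.finite(s) || s < 0 || s > 1) {
    stop("`s` must be a probability in [0, 1]", call. = FALSE)
  }
  bound_report("watts_strogatz", (s + 1 / k) / (2 * s + 1 / n),
               "approximation", list(n = n, k = k, s = s))
}

#' Degree-heterogeneity upper bound on the index
#'
#' For large networks the index is bounded above by the reciprocal of the
#' normalized degree heterogeneity: \eqn{\Delta(G) \le \langle k \rangle^2 /
#' \langle k^2 \rangle}. Equals 1 exactly on regular graphs and is below 1
#' otherwise (Cauchy-Schwarz): degree inequality suppresses diversity.
#'
#' @param stats a `network_stats` object (see [network_statistics()]) or an
#'   igraph.
#' @return a `bound_report` object with `kind = "upper_bound"`.
#' @export
heterogeneity_ratio_bound <- function(stats) {
  if (igraph::is_igraph(stats)) stats <- network_statistics(stats)
  value <- stats$mean_degree^2 / stats$second_moment
  bound_report("generic", value, "upper_bound",
               list(mean_degree = stats$mean_degree,
                    second_moment = stats$second_moment))
}

#' Meeting-time bound expressions
#'
#' Evaluates the two asymptotic meeting-time bounds as plain expression
#' values, without the unknown asymptotic constants: the spectral upper
#' bound \eqn{(1/(1-\lambda_2)) (2 \log |V| + |V| \langle k \rangle^2 /
#' \langle k^2 \rangle)} and the lower bound \eqn{|E| / D_{max}}. These are
#' order-of-magnitude diagnostics, not certified bounds.
#'
#' @param g a connected undirected igraph (small enough for
#'   [spectral_info()]).
#' @param spectral optional precomputed [spectral_info()] result.
#' @param stats optional precomputed [network_statistics()] result.
#' @return a list of two `bound_report` objects, `upper` and `lower`, in units of
#'   steps (meeting time, not the index).
#' @export
meeting_time_bounds <- function(g, spectral = NULL, stats = NULL) {
  if (is.null(spectral)) spectral <- spectral_info(g)
  if (is.null(stats)) stats <- network_statistics(g)
  n <- stats$size
  upper <- spectral$relaxation_factor *
    (2 * log(n) + n * stats$mean_degree^2 / stats$second_moment)
  lower <- stats$n_edges / stats$max_degree
  list(
    upper = bound_report("generic", upper, "upper_bound",
                         list(n = n, lambda2 = spectral$lambda2)),
    lower = bound_report("generic", lower, "lower_bound_expression",
                         list(n_edges = stats$n_edges,
                              max_degree = stats$max_degree))
  )
}

#' Fit the size-exponent scaling of the scale-free index
#'
#' Ordinary least squares of `log(delta)` on
#' `x = log(n^(-(3 - gamma)/(gamma - 1))) = -((3 - gamma)/(gamma - 1)) log n`,
#' the logarithm of the theoretical size-exponent bound. The fitted model is
#' \eqn{\Delta = b \, n^{-a (3-\gamma)/(\gamma-1)}}: `a` is the slope, `b`
#' the exponentiated intercept.
#'
#' @param gammas power-law exponents, all in (2, 3).
#' @param deltas positive index values, same length.
#' @param n network size(s); scalar or one per entry.
#' @return a list with `a`, `b`, `r_squared` and the fitted `lm` object.
#' @export
fit_scalefree_scaling <- function(gammas, deltas, n) {
  if (length(gammas) != length(deltas) || length(gammas) < 3) {
    stop("need >= 3 paired (gamma, delta) observations", call. = FALSE)
  }
  if (any(gammas <= 2) || any(gammas >= 3)) {
    stop("all `gammas` must lie strictly between 2 and 3", call. = FALSE)
  }
  if (any(deltas <= 0)) stop("all `deltas` must be positive", call. = FALSE)
  x <- -((3 - gammas) / (gammas - 1)) * log(n)
  if (var(x) < .Machine$double.eps) {
    stop("degenerate design: no variance in the bound exponent", call. = FALSE)
  }
  fit <- lm(log(deltas) ~ x)
  list(a = unname(coef(fit)[2]), b = unname(exp(coef(fit)[1])),
       r_squared = summary(fit)$r.squared, fit = fit)
}
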