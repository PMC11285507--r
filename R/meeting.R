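#' Sample meeting times of two synchronous random walks
#'
#' Two walkers start at independent uniformly random vertices; at each step
#' both simultaneously move to a uniformly random neighbour. The meeting time
#' is the first step at which they occupy the same vertex (0 if the starts
#' coincide). Meeting means co-location after the synchronous move; crossing
#' an edge in opposite directions is not a meeting.
#'
#' @param g a connected undirected igraph.
#' @param n_realizations number of independent realizations.
#' @param smax censoring horizon in steps; runs that have not met by `smax`
#'   return `NA`.
#' @param lazy if `TRUE` each walker independently stays put with probability
#'   1/2 each step. This removes the parity obstruction on bipartite graphs
#'   but changes the time scale; it is an extension, never used by the
#'   standard index.
#' @return integer vector of length `n_realizations`; `NA` marks censoring.
#' @export
sample_meeting_times <- function(g, n_realizations, smax, lazy = FALSE) {
  assert_connected(g, "meeting-time sampling")
  n_realizations <- assert_count(n_realizations, "n_realizations")
  smax <- assert_count(smax, "smax")
  csr <- graph_csr(g)
  cpp_meeting_times(csr$offsets, csr$neighbors, csr$n, n_realizations, smax,
                    lazy)
}

#' Estimate the structural diversity index by coalescing random walks
#'
#' The structural diversity index of a connected network `G` is
#' \deqn{\Delta(G) = \langle M_G \rangle / |V(G)|,} the expected meeting time
#' of two uniformly started synchronous random walks divided by the vertex
#' count. It benchmarks against the complete graph (\eqn{\Delta = 1}):
#' networks above 1 amplify long-run cultural diversity, networks below 1
#' suppress it.
#'
#' `n_realizations` independent meeting times are simulated, censored at
#' `smax = smax_multiplier * |V(G)|` steps. The meeting-time tail is close to
#' geometric, so censored runs are handled by right-censored geometric
#' maximum likelihood: the success probability is estimated as
#' `p = (observed meetings) / (total steps walked, censored runs counting
#' smax)`, and each censored run is imputed as `smax` plus a fresh
#' geometric(p) draw (memorylessness), rather than plugging in a conditional
#' mean.
#'
#' Bipartite graphs are refused by default: from odd-parity starts two
#' synchronous walkers can never meet. Set `lazy = TRUE` (with
#' `allow_bipartite = TRUE`) for a lazy-walk variant that breaks the parity;
#' this changes the time scale and is an extension outside the standard
#' index definition.
#'
#' @param g a connected undirected igraph.
#' @param n_realizations number of realizations (default `1e4`).
#' @param smax_multiplier censoring horizon in units of `|V(G)|`
#'   (default 100).
#' @param allow_bipartite allow bipartite input (see Details).
#' @param lazy lazy-walk variant (see [sample_meeting_times()]).
#' @return an object of class `meeting_estimate`: a list with
#'   `mean_meeting_time`, `delta`, `std_error` (of `mean_meeting_time`;
#'   divide by `|V|` for the error of `delta`), `n_censored`,
#'   `tail_success_prob`, `n_realizations`, `n_vertices`, `smax`.
#' @references The estimator and index follow the meeting-time/coalescence
#'   duality for the voter model; see the package vignette.
#' @export
#' @examples
#' set.seed(1)
#' est <- estimate_delta(graph_complete(50), n_realizations = 2000)
#' est$delta # close to 1
estimate_delta <- function(g, n_realizations = 10000, smax_multiplier = 100,
                           allow_bipartite = FALSE, lazy = FALSE) {
  assert_connected(g, "estimate_delta()")
  assert_count(smax_multiplier, "smax_multiplier")
  if (!allow_bipartite && is_two_colourable(g)) {
    stop("graph is bipartite: synchronous walkers started at odd parity can ",
         "never meet, so the meeting time is infinite. Use allow_bipartite ",
         "= TRUE with lazy = TRUE for a lazy-walk variant.", call. = FALSE)
  }
  n <- igraph::vcount(g)
  smax <- smax_multiplier * n
  times <- sample_meeting_times(g, n_realizations, smax, lazy = lazy)
  censored <- is.na(times)
  n_cens <- sum(censored)
  if (n_cens == n_realizations) {
    stop("all runs censored: no observed meetings within smax = ", smax,
         " steps; the geometric tail is unidentifiable", call. = FALSE)
  }
  p_hat <- 1
  if (n_cens > 0) {
    total_steps <- sum(times[!censored]) + n_cens * smax
    p_hat <- sum(!censored) / total_steps
    times[censored] <- smax + rgeom(n_cens, p_hat) + 1
  }
  times <- as.numeric(times)
  m <- mean(times)
  structure(list(
    mean_meeting_time = m,
    delta = m / n,
    std_error = sd(times) / sqrt(n_realizations),
    n_censored = n_cens,
    tail_success_prob = if (n_cens > 0) p_hat else NA_real_,
    n_realizations = n_realizations,
    n_vertices = n,
    smax = smax
  ), class = "meeting_estimate")
}

#' @export
print.meeting_estimate <- function(x, ...) {
  cat("Structural diversity index estimate\n")
  cat(sprintf("  delta     %.4f (se %.4f)\n", x$delta,
              x$std_error / x$n_vertices))
  cat(sprintf("  <M_G>     %.2f steps (se %.2f), |V| = %d\n",
              x$mean_meeting_time, x$std_error, x$n_vertices))
  cat(sprintf("  %d realizations, %d censored at smax = %d",
              x$n_realizations, x$n_censored, x$smax))
  if (x$n_censored > 0) {
    cat(sprintf(" (tail p = %.3g)", x$tail_success_prob))
  }
  cat("\n")
  invisible(x)
}

#' Exact expected meeting time on small graphs
#'
#' Independent oracle for the quantity estimated by [estimate_delta()]:
#' solves the absorbing linear system for the synchronous product chain on
#' ordered vertex pairs (the diagonal is absorbing) and averages the expected
#' absorption time over independent uniform starts (coincident starts
#' contribute 0). Exact up to linear-solver tolerance; state space is
#' `|V|^2`, so the graph size is capped.
#'
#' @param g a connected, non-bipartite undirected igraph.
#' @param max_size largest vertex count accepted (default 50).
#' @return expected meeting time in steps (a single number).
#' @export
#' @examples
#' exact_meeting_time(graph_complete(3)) # 8/3
exact_meeting_time <- function(g, max_size = 50) {
  assert_connected(g, "exact_meeting_time()")
  n <- igraph::vcount(g)
  if (n > max_size) {
    stop("pair-chain oracle limited to ", max_size, " vertices (state space ",
         "|V|^2)", call. = FALSE)
  }
  if (is_two_colourable(g)) {
    stop("graph is bipartite: the expected meeting time is infinite for ",
         "odd-parity starts", call. = FALSE)
  }
  A <- igraph::as_adjacency_matrix(g, sparse = FALSE)
  P <- A / igraph::degree(g)
  K <- kronecker(P, P) # product chain on ordered pairs, row (u-1)*n + v
  diag_states <- (seq_len(n) - 1) * n + seq_len(n)
  trans <- setdiff(seq_len(n^2), diag_states)
  Q <- K[trans, trans, drop = FALSE]
  h <- solve(diag(length(trans)) - Q, rep(1, length(trans)))
  sum(h) / n^2
}

#' Probability that two halting walks meet before either halts
#'
#' An `r`-halting walk is a simple random walk that halts at each step with
#' probability `r`. This estimates \eqn{p_r(\infty) = P(M_G < \min(S_1,
#' S_2))}, the probability that two such walks from independent uniform
#' starts meet (synchronously co-occupy a vertex) strictly before either
#' halts; coincident starts count as met. For small `r` this is close to
#' \eqn{e^{-2 r \langle M_G \rangle}}, which is the bridge between meeting
#' times and long-run diversity.
#'
#' @param g a connected undirected igraph.
#' @param r per-step halting probability, in (0, 1).
#' @param n_realizations Monte-Carlo sample size.
#' @return a list with `p_meet`, `std_error` and `n_realizations`.
#' @export
halting_meet_probability <- function(g, r, n_realizations = 10000) {
  assert_connected(g, "halting_meet_probability()")
  if (!is.finite(r) || r <= 0 || r >= 1) {
    stop("`r` must lie strictly between 0 and 1", call. = FALSE)
  }
  n_realizations <- assert_count(n_realizations, "n_realizations")
  csr <- graph_csr(g)
  tmax <- max(1000L, as.integer(ceiling(200 / r)))
  res <- cpp_halting_meet_times(csr$offsets, csr$neighbors, csr$n, r,
                                n_realizations, tmax)
  met <- !is.na(res) & res >= 0
  p <- mean(met)
  list(p_meet = p,
       std_error = sqrt(p * (1 - p) / n_realizations),
       n_realizations = n_realizations)
}

# Internal: meeting-within-t curve for the duality experiment.
# Returns P(meet within t steps, before either halt) for t = 0..horizon.
halting_meet_curve <- function(g, r, horizon, n_realizations) {
  csr <- graph_csr(g)
  tmax <- max(horizon, as.integer(ceiling(200 / r)))
  res <- cpp_halting_meet_times(csr$offsets, csr$neighbors, csr$n, r,
                                n_realizations, tmax)
  met <- !is.na(res) & res >= 0
  vapply(0:horizon, function(t) mean(met & res <= t), numeric(1))
}
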