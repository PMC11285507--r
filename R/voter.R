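#' Simpson diversity of a meme configuration
#'
#' `1 - sum_m p_m^2` over the empirical meme frequencies: the probability
#' that two individuals drawn uniformly at random (with replacement) display
#' different memes. 0 for a homogeneous population, at most `1 - 1/n` for `n`
#' individuals.
#'
#' @param labels vector of per-individual meme labels (any atomic type).
#' @return Simpson diversity in `[0, 1]`.
#' @export
#' @examples
#' simpson_diversity(1:6)          # 0.8333
#' simpson_diversity(c(1, 1, 1, 2, 2, 2)) # 0.5
simpson_diversity <- function(labels) {
  if (length(labels) == 0) stop("empty label vector", call. = FALSE)
  p <- tabulate(match(labels, unique(labels))) / length(labels)
  1 - sum(p^2)
}

#' One synchronous step of the voter model with innovation
#'
#' Every vertex independently either invents a fresh, never-used meme (with
#' probability `r`; infinite-alleles innovation from a monotone counter) or
#' copies the current (time-t) meme of a uniformly chosen neighbour. All
#' updates are applied simultaneously (double-buffered).
#'
#' @param labels numeric vector of current meme labels, one per vertex.
#' @param g a connected undirected igraph (every vertex needs a neighbour).
#' @param r innovation probability in `[0, 1]`.
#' @param next_label smallest label value not yet used.
#' @return a list with the updated `labels` and `next_label`.
#' @export
voter_step <- function(labels, g, r, next_label = max(labels) + 1) {
  if (length(labels) != igraph::vcount(g)) {
    stop("`labels` must have one entry per vertex", call. = FALSE)
  }
  if (min(igraph::degree(g)) == 0) {
    stop("isolated vertex: cannot imitate a neighbour", call. = FALSE)
  }
  if (!is.finite(r) || r < 0 || r > 1) {
    stop("`r` must be a probability in [0, 1]", call. = FALSE)
  }
  csr <- graph_csr(g)
  res <- cpp_voter_run(csr$offsets, csr$neighbors, csr$n, as.numeric(labels),
                       as.numeric(next_label), r, 1L)
  list(labels = res$labels, next_label = res$next_label)
}

#' Simulate the voter model with innovation
#'
#' Starts from the all-distinct configuration (every individual displays its
#' own meme), runs `n_steps` synchronous updates per replicate, records the
#' Simpson diversity `D(t)` after every step, and averages over steps and
#' replicates to produce the long-run expected diversity `d_infinity`. No
#' burn-in is discarded by default (`burn_in = 0`); the plain time average
#' over `t = 1..n_steps` is the estimand.
#'
#' Exactly one of `r` (per-individual innovation probability) and `alpha`
#' (per-capita innovation rate, `alpha = r * |V|`) must be supplied.
#'
#' @param g a connected undirected igraph.
#' @param r innovation probability per individual and step, in `[0, 1]`.
#' @param alpha per-capita innovation rate; \eqn{r = \alpha / |V|}.
#' @param n_steps steps per replicate (default `10 * |V|`).
#' @param n_reps replicates (default 20).
#' @param burn_in steps discarded from the front of each replicate before
#'   averaging (default 0).
#' @return an object of class `diversity_trajectory`: a list with `d_series`
#'   (an `n_steps x n_reps` matrix of `D(t)`), `d_infinity`, `meme_counts`
#'   (abundance spectrum of the final configuration of each replicate, as a
#'   list), and the parameters used.
#' @export
#' @examples
#' set.seed(1)
#' traj <- run_voter(graph_complete(30), alpha = 1, n_reps = 3)
#' traj$d_infinity
run_voter <- function(g, r = NULL, alpha = NULL, n_steps = NULL, n_reps = 20,
                      burn_in = 0) {
  assert_connected(g, "run_voter()")
  n <- igraph::vcount(g)
  if (is.null(r) + is.null(alpha) != 1) {
    stop("supply exactly one of `r` and `alpha`", call. = FALSE)
  }
  if (is.null(r)) r <- alpha / n
  if (!is.finite(r) || r < 0 || r > 1) {
    stop("`r` must be a probability in [0, 1] (alpha <= |V|)", call. = FALSE)
  }
  if (is.null(n_steps)) n_steps <- 10 * n
  n_steps <- assert_count(n_steps, "n_steps")
  n_reps <- assert_count(n_reps, "n_reps")
  if (burn_in >= n_steps) stop("`burn_in` must be < n_steps", call. = FALSE)
  csr <- graph_csr(g)
  d <- matrix(NA_real_, n_steps, n_reps)
  meme_counts <- vector("list", n_reps)
  for (rep in seq_len(n_reps)) {
    res <- cpp_voter_run(csr$offsets, csr$neighbors, csr$n,
                         as.numeric(seq_len(n)), as.numeric(n + 1), r,
                         n_steps)
    d[, rep] <- res$d_series
    meme_counts[[rep]] <- sort(as.integer(table(res$labels)),
                               decreasing = TRUE)
  }
  keep <- if (burn_in > 0) -(seq_len(burn_in)) else TRUE
  structure(list(
    d_series = d,
    d_infinity = mean(d[keep, , drop = FALSE]),
    meme_counts = meme_counts,
    r = r, alpha = r * n, n_steps = n_steps, n_reps = n_reps,
    burn_in = burn_in, n_vertices = n
  ), class = "diversity_trajectory")
}

#' @export
print.diversity_trajectory <- function(x, ...) {
  cat("Voter-model diversity trajectory\n")
  cat(sprintf("  |V| = %d, r = %.4g (alpha = %.3g), %d steps x %d reps\n",
              x$n_vertices, x$r, x$alpha, x$n_steps, x$n_reps))
  cat(sprintf("  D_infinity = %.4f\n", x$d_infinity))
  invisible(x)
}

#' Duality experiment: voter-model homogeneity vs halting-walk meetings
#'
#' The voter model with innovation is dual to a pair of `r`-halting random
#' walks: the probability that two uniformly sampled individuals share a meme
#' at time `t`, `1 - D(t)`, equals the probability `p_r(t)` that two halting
#' walks from uniform starts meet within `t` steps before either halts. This
#' function estimates both curves by Monte Carlo and reports the pointwise
#' gaps with z-scores against the combined standard errors.
#'
#' @param g a connected, non-bipartite undirected igraph, small enough for
#'   tight Monte-Carlo error.
#' @param r innovation/halting probability in (0, 1).
#' @param horizon largest time `t` compared.
#' @param n_reps_voter voter-model replicates.
#' @param n_reps_walk halting-walk realizations.
#' @return a list with `table` (a data frame with columns `t`,
#'   `one_minus_d`, `se_voter`, `p_r`, `se_walk`, `gap`, `z`) and
#'   `max_abs_z`.
#' @export
duality_check <- function(g, r, horizon = 50, n_reps_voter = 4000,
                          n_reps_walk = 40000) {
  assert_connected(g, "duality_check()")
  n <- igraph::vcount(g)
  csr <- graph_csr(g)
  one_minus_d <- matrix(NA_real_, horizon, n_reps_voter)
  for (rep in seq_len(n_reps_voter)) {
    res <- cpp_voter_run(csr$offsets, csr$neighbors, csr$n,
                         as.numeric(seq_len(n)), as.numeric(n + 1), r,
                         horizon)
    one_minus_d[, rep] <- 1 - res$d_series
  }
  v_mean <- c(1 / n, rowMeans(one_minus_d)) # t = 0: all memes distinct
  v_se <- c(0, apply(one_minus_d, 1, sd) / sqrt(n_reps_voter))
  p_curve <- halting_meet_curve(g, r, horizon, n_reps_walk)
  w_se <- sqrt(p_curve * (1 - p_curve) / n_reps_walk)
  gap <- v_mean - p_curve
  z <- gap / sqrt(v_se^2 + w_se^2)
  z[!is.finite(z)] <- 0 # t = 0 is the same event on both sides
  tab <- data.frame(t = 0:horizon, one_minus_d = v_mean, se_voter = v_se,
                    p_r = p_curve, se_walk = w_se, gap = gap, z = z)
  list(table = tab, max_abs_z = max(abs(z)))
}
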