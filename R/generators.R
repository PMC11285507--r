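#' Complete graph
#'
#' @param n number of vertices (>= 2).
#' @return the complete graph on `n` vertices as an igraph.
#' @export
graph_complete <- function(n) {
  n <- assert_count(n, "n", min = 2)
  igraph::make_full_graph(n, directed = FALSE)
}

#' Watts-Strogatz small-world graph
#'
#' Starts from a ring lattice in which every vertex is linked to its `k/2`
#' nearest neighbours on each side, then rewires the far endpoint of each
#' original edge independently with probability `s` to a uniformly random
#' vertex, avoiding self-loops and duplicate edges. The edge count `n*k/2` is
#' conserved for every `s`. Connectivity is checked and generation retried
#' (up to `max_tries`) if the rewired graph is disconnected.
#'
#' Randomness comes from the R session RNG; call [set.seed()] for
#' reproducibility.
#'
#' @param n number of vertices.
#' @param k even mean degree, `k < n`.
#' @param s rewiring probability in `[0, 1]`.
#' @param max_tries regeneration attempts before giving up.
#' @return an igraph.
#' @export
#' @examples
#' set.seed(1)
#' g <- graph_watts_strogatz(100, 6, 0.01)
#' igraph::ecount(g) # 300
graph_watts_strogatz <- function(n, k, s, max_tries = 100) {
  n <- assert_count(n, "n", min = 3)
  k <- assert_count(k, "k", min = 2)
  if (k %% 2 != 0) stop("`k` must be even", call. = FALSE)
  if (k >= n) stop("`k` must be smaller than `n`", call. = FALSE)
  if (!is.finite(s) || s < 0 || s > 1) {
    stop("`s` must be a probability in [0, 1]", call. = FALSE)
  }
  u0 <- rep(seq_len(n), k / 2)
  v0 <- u0 + rep(seq_len(k / 2), each = n)
  v0 <- ((v0 - 1) %% n) + 1
  for (try in seq_len(max_tries)) {
    u <- u0
    v <- v0
    # adjacency hash for duplicate avoidance
    key <- function(a, b) pmin(a, b) * (n + 1) + pmax(a, b)
    present <- new.env(hash = TRUE, parent = emptyenv())
    for (kk in key(u, v)) assign(as.character(kk), TRUE, envir = present)
    rewire <- which(stats::runif(length(u)) < s)
    for (i in rewire) {
      # draw a replacement far endpoint for edge (u[i], v[i])
      for (attempt in 1:100) {
        w <- sample.int(n, 1)
        if (w == u[i]) next
        kk <- as.character(key(u[i], w))
        if (exists(kk, envir = present, inherits = FALSE)) next
        rm(list = as.character(key(u[i], v[i])), envir = present)
        assign(kk, TRUE, envir = present)
        v[i] <- w
        break
      }
    }
    g <- igraph::make_empty_graph(n, directed = FALSE)
    g <- igraph::add_edges(g, rbind(u, v))
    if (igraph::is_connected(g)) return(g)
  }
  stop("failed to generate a connected Watts-Strogatz graph in ", max_tries,
       " tries (n=", n, ", k=", k, ", s=", s, ")", call. = FALSE)
}

#' Power-law configuration-model graph
#'
#' Draws a degree sequence from `P(k) ~ k^(-gamma)` on `k = kmin..n-1` (one
#' randomly chosen degree is incremented if the sum is odd), pairs stubs with
#' the configuration model, erases self-loops and multi-edges, and returns
#' the largest connected component. The realized minimum degree can fall
#' below `kmin` only through erasure or the component restriction; a message
#' reports when it does.
#'
#' @param n number of vertices before erasure/component restriction.
#' @param gamma power-law exponent (> 1); smaller values give heavier tails.
#' @param kmin minimum degree of the sampled sequence.
#' @return an igraph (the largest connected component).
#' @export
#' @examples
#' set.seed(1)
#' g <- graph_scale_free(300, gamma = 2.5, kmin = 4)
graph_scale_free <- function(n, gamma, kmin = 4) {
  n <- assert_count(n, "n", min = 10)
  kmin <- assert_count(kmin, "kmin", min = 1)
  if (!is.finite(gamma) || gamma <= 1) stop("`gamma` must be > 1", call. = FALSE)
  if (kmin >= n) stop("`kmin` must be smaller than `n`", call. = FALSE)
  ks <- kmin:(n - 1)
  degs <- sample(ks, n, replace = TRUE, prob = ks^(-gamma))
  if (sum(degs) %% 2 == 1) {
    i <- sample(which(degs < n - 1), 1)
    degs[i] <- degs[i] + 1
  }
  g <- igraph::sample_degseq(degs, method = "configuration")
  g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
  g <- largest_component(g)
  realized_min <- min(igraph::degree(g))
  if (realized_min < kmin) {
    message("erasure/component restriction lowered the minimum degree to ",
            realized_min, " (requested kmin = ", kmin, ")")
  }
  g
}
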