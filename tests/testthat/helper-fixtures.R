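# Fixture graphs built in code. All are connected; bipartiteness noted.

ring_lattice <- function(n, k) {
  u <- rep(seq_len(n), k / 2)
  v <- ((u + rep(seq_len(k / 2), each = n)) - 1) %% n + 1
  g <- igraph::make_empty_graph(n, directed = FALSE)
  igraph::add_edges(g, rbind(u, v))
}

# hub joined to a, b, c plus edge a-b: degrees (3, 2, 2, 1)
hub_triangle <- function() {
  igraph::graph_from_edgelist(
    rbind(c(1, 2), c(1, 3), c(1, 4), c(2, 3)), directed = FALSE)
}

petersen <- function() igraph::make_graph("Petersen")

# connected non-bipartite graphs with <= 25 vertices for oracle comparisons
oracle_battery <- function() {
  set.seed(99)
  list(
    k3 = graph_complete(3),
    k5 = graph_complete(5),
    c9 = igraph::make_ring(9),           # odd cycle
    ring_20_4 = ring_lattice(20, 4),     # triangles
    petersen = petersen(),
    ws_24 = graph_watts_strogatz(24, 4, 0.2),
    hub = hub_triangle()                 # contains a triangle
  )
}

# z-score of a Monte-Carlo delta estimate against a reference value
delta_z <- function(est, reference) {
  (est$delta - reference) / (est$std_error / est$n_vertices)
}
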