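test_that("edge-list reading maps tokens, drops self-loops and duplicates", {
  f <- withr::local_tempfile()
  writeLines(c("a b", "b c", "# a comment"), f)
  g <- read_edgelist(f)
  expect_equal(igraph::vcount(g), 3)
  expect_equal(igraph::ecount(g), 2)
  expect_setequal(igraph::V(g)$name, c("a", "b", "c"))

  writeLines(c("a b", "b a", "a a"), f)
  warns <- capture_warnings(g2 <- read_edgelist(f))
  expect_length(warns, 2)
  expect_match(warns, "self-loop|duplicate", all = TRUE)
  expect_equal(igraph::vcount(g2), 2)
  expect_equal(igraph::ecount(g2), 1)

  writeLines(c("a b", "c"), f)
  expect_error(read_edgelist(f), "line 2")
  writeLines("# only comments", f)
  expect_error(read_edgelist(f), "empty")
})

test_that("edge-list write/read round-trip preserves the edge set", {
  set.seed(1)
  g <- graph_watts_strogatz(50, 4, 0.2)
  igraph::V(g)$name <- paste0("v", seq_len(50))
  f <- withr::local_tempfile()
  write_edgelist(g, f)
  g2 <- read_edgelist(f)
  key <- function(gr) {
    el <- igraph::as_edgelist(gr)
    sort(paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2])))
  }
  expect_identical(key(g2), key(g))
})

test_that("largest_component keeps the right component and is idempotent", {
  # two equal triangles plus an isolate: first-seen triangle wins
  g <- igraph::graph_from_edgelist(
    rbind(c(1, 2), c(2, 3), c(3, 1), c(4, 5), c(5, 6), c(6, 4)),
    directed = FALSE)
  g <- igraph::add_vertices(g, 1)
  igraph::V(g)$name <- paste0("v", 1:7)
  lcc <- largest_component(g)
  expect_equal(igraph::vcount(lcc), 3)
  expect_setequal(igraph::V(lcc)$name, c("v1", "v2", "v3"))
  # idempotence / connected input unchanged
  lcc2 <- largest_component(lcc)
  expect_equal(igraph::ecount(lcc2), igraph::ecount(lcc))
  # path a-b plus path c-d-e
  h <- igraph::graph_from_edgelist(rbind(c(1, 2), c(3, 4), c(4, 5)),
                                   directed = FALSE)
  expect_equal(igraph::vcount(largest_component(h)), 3)
})

test_that("complete-graph generator has the full edge set", {
  expect_equal(igraph::ecount(graph_complete(4)), 6)
  expect_equal(network_statistics(graph_complete(4))$edge_density, 1)
  expect_equal(network_statistics(graph_complete(3))$clustering_global, 1)
  expect_true(all(igraph::degree(graph_complete(100)) == 99))
  expect_error(graph_complete(1), ">= 2")
})

test_that("Watts-Strogatz generator conserves the edge budget", {
  g0 <- graph_watts_strogatz(10, 4, 0)
  expect_true(all(igraph::degree(g0) == 4))
  set.seed(3)
  g <- graph_watts_strogatz(1000, 6, 0.01)
  expect_equal(igraph::ecount(g), 3000) # n*k/2 for every s
  expect_equal(network_statistics(g)$mean_degree, 6)
  # s = 0, k = 2 is the even cycle, hence bipartite
  expect_true(network_statistics(graph_watts_strogatz(6, 2, 0))$is_bipartite)
  expect_error(graph_watts_strogatz(10, 3, 0.1), "even")
  expect_error(graph_watts_strogatz(10, 10, 0.1), "smaller")
  expect_error(graph_watts_strogatz(10, 4, 1.5), "probability")
})

test_that("scale-free generator is seeded-deterministic with tunable tail", {
  set.seed(5)
  g1 <- suppressMessages(graph_scale_free(200, 2.5, 4))
  set.seed(5)
  g2 <- suppressMessages(graph_scale_free(200, 2.5, 4))
  expect_identical(igraph::as_edgelist(g1), igraph::as_edgelist(g2))
  # steep exponent: almost-regular degree sequence
  set.seed(6)
  greg <- suppressMessages(graph_scale_free(300, 10, 4))
  expect_lt(network_statistics(greg)$kappa_normalized, 1.05)
  # heavy tail raises normalized heterogeneity well above the regular value
  set.seed(6)
  gheavy <- suppressMessages(graph_scale_free(300, 2.2, 4))
  expect_gt(network_statistics(gheavy)$kappa_normalized, 2)
  expect_error(graph_scale_free(200, 0.5, 4), "gamma")
  expect_error(graph_scale_free(200, 2.5, 300), "kmin")
})

test_that("network statistics match hand-computed values", {
  path3 <- igraph::make_graph(~ a - b - c)
  st <- network_statistics(path3)
  expect_equal(st$wiener_index, 4) # 1 + 1 + 2
  expect_equal(st$edge_density, 2 / 3)

  star <- igraph::make_star(4, mode = "undirected")
  st <- network_statistics(star) # degrees 3,1,1,1
  expect_equal(st$kappa_moment_ratio, 2)
  expect_equal(st$kappa_normalized, 4 / 3)

  st <- network_statistics(graph_complete(3))
  expect_equal(st$wiener_index, 3)
  expect_equal(st$clustering_global, 1)
  expect_equal(st$kappa_normalized, 1)

  # Wiener index of K_n is the number of unordered pairs
  for (n in c(4, 7, 12)) {
    expect_equal(network_statistics(graph_complete(n))$wiener_index,
                 n * (n - 1) / 2)
  }

  disconnected <- igraph::graph_from_edgelist(rbind(c(1, 2), c(3, 4)),
                                              directed = FALSE)
  st <- network_statistics(disconnected)
  expect_false(st$is_connected)
  expect_identical(st$wiener_index, Inf)
  expect_equal(st$mean_degree, 1)
})

test_that("kappa_normalized equals 1 exactly on regular graphs", {
  for (g in list(graph_complete(8), igraph::make_ring(9),
                 ring_lattice(12, 4))) {
    expect_equal(network_statistics(g)$kappa_normalized, 1)
  }
})

test_that("walk-operator spectra match closed forms", {
  expect_equal(spectral_info(graph_complete(4))$lambda2, -1 / 3,
               tolerance = 1e-10)
  expect_equal(spectral_info(igraph::make_ring(6))$lambda2, cos(2 * pi / 6),
               tolerance = 1e-10)
  expect_equal(spectral_info(graph_complete(2))$lambda2, -1,
               tolerance = 1e-10)
  expect_error(spectral_info(graph_complete(20), max_size = 10), "too large")
})
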