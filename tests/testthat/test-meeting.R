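test_that("pair-chain oracle reproduces closed-form complete-graph values", {
  expect_equal(exact_meeting_time(graph_complete(3)), 8 / 3,
               tolerance = 1e-10)
  expect_equal(exact_meeting_time(graph_complete(4)), 27 / 8,
               tolerance = 1e-10)
  # general closed form: (1 - 1/n) (n-1)^2 / (n-2)
  for (n in c(5, 10, 20)) {
    expect_equal(exact_meeting_time(graph_complete(n)),
                 (1 - 1 / n) * (n - 1)^2 / (n - 2), tolerance = 1e-9)
  }
  expect_error(exact_meeting_time(graph_complete(2)), "bipartite")
  expect_error(exact_meeting_time(graph_complete(20), max_size = 10),
               "limited")
})

test_that("meeting sampler handles coincident starts and parity censoring", {
  set.seed(1)
  # K2: coincident starts meet at 0, distinct starts swap forever
  times <- sample_meeting_times(graph_complete(2), 500, smax = 1000,
                                lazy = FALSE)
  expect_true(all(times[!is.na(times)] == 0))
  expect_gt(sum(is.na(times)), 0)
  expect_gt(sum(times == 0, na.rm = TRUE), 0)
})

test_that("complete-graph meeting times from distinct starts are geometric", {
  set.seed(2)
  n <- 5
  times <- sample_meeting_times(graph_complete(n), 20000, smax = 5000)
  positive <- times[times > 0] # distinct starts
  p <- (n - 2) / (n - 1)^2
  expect_equal(mean(positive), 1 / p, tolerance = 0.05)
  # chi-squared goodness of fit against Geometric(p) on {1, 2, ...}
  kmax <- 30
  obs <- tabulate(pmin(positive, kmax + 1), nbins = kmax + 1)
  probs <- c(dgeom(0:(kmax - 1), p), 1 - pgeom(kmax - 1, p))
  gof <- chisq.test(obs, p = probs)
  expect_gt(gof$p.value, 0.01)
})

test_that("Monte-Carlo delta matches the exact value on the complete graph", {
  set.seed(3)
  est <- estimate_delta(graph_complete(100), n_realizations = 10000)
  exact <- (1 - 1 / 100) * 99^2 / (98 * 100)
  expect_lt(abs(delta_z(est, exact)), 3)
  expect_equal(est$delta, est$mean_meeting_time / 100)
  expect_equal(est$n_realizations, 10000)
})

test_that("delta estimates agree with the pair-chain oracle on all fixtures", {
  battery <- oracle_battery()
  set.seed(4)
  for (nm in names(battery)) {
    g <- battery[[nm]]
    exact <- exact_meeting_time(g)
    est <- estimate_delta(g, n_realizations = 20000)
    expect_lt(abs(est$mean_meeting_time - exact) / est$std_error, 3.5,
              label = sprintf("z-score on fixture %s", nm))
  }
})

test_that("censoring imputation is consistent across smax choices", {
  # odd cycle: slow meeting, real censoring at a short horizon
  g <- igraph::make_ring(41)
  set.seed(5)
  short <- estimate_delta(g, n_realizations = 8000, smax_multiplier = 20)
  long <- estimate_delta(g, n_realizations = 8000, smax_multiplier = 2000)
  expect_gt(short$n_censored, 0)
  expect_equal(long$n_censored, 0)
  se <- sqrt(short$std_error^2 + long$std_error^2)
  expect_lt(abs(short$mean_meeting_time - long$mean_meeting_time) / se, 3.5)
  expect_true(short$tail_success_prob > 0 && short$tail_success_prob <= 1)
})

test_that("delta estimation is invariant under vertex relabeling", {
  g <- petersen()
  perm <- c(4, 7, 1, 10, 3, 6, 9, 2, 5, 8)
  gp <- igraph::permute(g, perm)
  expect_equal(exact_meeting_time(gp), exact_meeting_time(g),
               tolerance = 1e-9)
  set.seed(6)
  e1 <- estimate_delta(g, 20000)
  e2 <- estimate_delta(gp, 20000)
  se <- sqrt(e1$std_error^2 + e2$std_error^2)
  expect_lt(abs(e1$mean_meeting_time - e2$mean_meeting_time) / se, 3.5)
})

test_that("bipartite graphs are refused unless the lazy walk is requested", {
  g <- igraph::make_ring(6) # even cycle
  expect_error(estimate_delta(g), "parity")
  set.seed(7)
  est <- estimate_delta(g, n_realizations = 2000, allow_bipartite = TRUE,
                        lazy = TRUE)
  expect_true(is.finite(est$delta) && est$delta > 0)
})

test_that("an unidentifiable tail (no observed meetings) is an error", {
  # even cycle, no coincident starts at this seed, horizon too short to meet
  g <- igraph::make_ring(100)
  set.seed(9)
  expect_error(
    estimate_delta(g, n_realizations = 20, smax_multiplier = 1,
                   allow_bipartite = TRUE),
    "unidentifiable")
})

test_that("halting-walk meet probability behaves at both r extremes", {
  g <- graph_complete(3)
  # r near 1: only coincident starts meet, p ~ 1/|V|
  set.seed(9)
  hp <- halting_meet_probability(g, r = 0.999, n_realizations = 20000)
  expect_equal(hp$p_meet, 1 / 3, tolerance = 0.03)
  # small r: close to exp(-2 r <M_G>) with <M_K3> = 8/3
  set.seed(10)
  hp <- halting_meet_probability(g, r = 0.02, n_realizations = 100000)
  expect_equal(hp$p_meet, exp(-2 * 0.02 * 8 / 3), tolerance = 0.02)
  expect_error(halting_meet_probability(g, r = 0), "strictly")
  expect_error(halting_meet_probability(g, r = 1.2), "strictly")
})
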