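#' Standardized log-log ordinary least squares
#'
#' Regression used to relate the (log) structural diversity index to (log)
#' network covariates on comparable scales: every variable is
#' log-transformed and then z-scored, and an OLS fit with intercept is run
#' (the intercept is then ~0 by construction). Standardization makes the
#' coefficients directly comparable across predictors.
#'
#' @param response strictly positive numeric vector.
#' @param predictors named list or data frame of strictly positive numeric
#'   vectors, same length as `response`.
#' @return an object of class `regression_result`: a list with
#'   `coefficients` (a data frame: estimate, std_error, t, p_value per term),
#'   `r_squared`, `adj_r_squared`, `n_observations`, and the `lm` fit.
#' @export
#' @examples
#' x <- exp(rnorm(50))
#' standardized_loglog_ols(x^2, list(x = x))$coefficients
standardized_loglog_ols <- function(response, predictors) {
  predictors <- as.data.frame(predictors)
  if (any(response <= 0)) {
    stop("`response` must be strictly positive for the log transform",
         call. = FALSE)
  }
  for (nm in names(predictors)) {
    if (any(predictors[[nm]] <= 0)) {
      stop("predictor `", nm, "` must be strictly positive for the log ",
           "transform", call. = FALSE)
    }
  }
  n <- length(response)
  if (nrow(predictors) != n || n < ncol(predictors) + 2) {
    stop("need n >= number of predictors + 2 observations", call. = FALSE)
  }
  z <- function(v) as.numeric(scale(log(v)))
  dat <- data.frame(lapply(predictors, z))
  dat$.y <- z(response)
  fit <- lm(.y ~ ., data = dat)
  if (any(is.na(coef(fit)))) {
    stop("collinear design: some coefficients are not estimable",
         call. = FALSE)
  }
  sm <- summary(fit)
  cf <- as.data.frame(sm$coefficients)
  names(cf) <- c("estimate", "std_error", "t", "p_value")
  structure(list(
    coefficients = cf,
    r_squared = sm$r.squared,
    adj_r_squared = sm$adj.r.squared,
    n_observations = n,
    fit = fit
  ), class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  stars <- function(p) ifelse(p < 0.001, "***",
                       ifelse(p < 0.01, "**", ifelse(p < 0.1, "*", "")))
  cat("Standardized log-log OLS (n =", x$n_observations, ")\n")
  cf <- x$coefficients
  for (i in seq_len(nrow(cf))) {
    cat(sprintf("  %-24s %8.3f (%.3f) %s\n", rownames(cf)[i],
                cf$estimate[i], cf$std_error[i], stars(cf$p_value[i])))
  }
  cat(sprintf("  R^2 %.3f, adjusted R^2 %.3f\n", x$r_squared,
              x$adj_r_squared))
  invisible(x)
}

#' Generate a reproducible synthetic network corpus
#'
#' Builds a mixed corpus of Watts-Strogatz and power-law
#' configuration-model networks spanning parameter ranges, with a manifest
#' describing each network. A stand-in for a real-network collection when
#' exercising corpus-level analyses (statistics tables, regressions,
#' intervention summaries).
#'
#' @param n_ws,n_sf number of Watts-Strogatz / scale-free networks.
#' @param size_range inclusive range of vertex counts to draw from.
#' @param ws_k mean degree for the WS family.
#' @param ws_s_range range of rewiring probabilities (sampled log-uniform).
#' @param sf_gamma_range range of power-law exponents (sampled uniform).
#' @param sf_kmin minimum degree for the scale-free family.
#' @return a list with `graphs` (named list of igraphs) and `manifest`
#'   (data frame: name, family, n_requested, n_realized, and the family
#'   parameter).
#' @export
synthetic_corpus <- function(n_ws = 10, n_sf = 10, size_range = c(100, 300),
                             ws_k = 6, ws_s_range = c(0.005, 0.3),
                             sf_gamma_range = c(2.2, 2.9), sf_kmin = 4) {
  graphs <- list()
  rows <- list()
  for (i in seq_len(n_ws)) {
    n <- sample(size_range[1]:size_range[2], 1)
    s <- exp(stats::runif(1, log(ws_s_range[1]), log(ws_s_range[2])))
    g <- graph_watts_strogatz(n, ws_k, s)
    nm <- sprintf("ws_%02d", i)
    graphs[[nm]] <- g
    rows[[length(rows) + 1]] <- data.frame(
      name = nm, family = "watts_strogatz", n_requested = n,
      n_realized = igraph::vcount(g), parameter = s)
  }
  for (i in seq_len(n_sf)) {
    n <- sample(size_range[1]:size_range[2], 1)
    gamma <- stats::runif(1, sf_gamma_range[1], sf_gamma_range[2])
    g <- suppressMessages(graph_scale_free(n, gamma, sf_kmin))
    nm <- sprintf("sf_%02d", i)
    graphs[[nm]] <- g
    rows[[length(rows) + 1]] <- data.frame(
      name = nm, family = "scale_free", n_requested = n,
      n_realized = igraph::vcount(g), parameter = gamma)
  }
  list(graphs = graphs, manifest = do.call(rbind, rows))
}

#' Run a scripted synthetic-network experiment
#'
#' Orchestrates the package's standard experiments at configurable scale and
#' returns machine-readable tables (no plotting).
#'
#' * `"scalefree_scaling"`: estimates the index over a grid of power-law
#'   exponents at fixed size and minimum degree, then fits the
#'   size-exponent scaling model with [fit_scalefree_scaling()].
#' * `"smallworld_rewiring"`: estimates the index over a grid of rewiring
#'   probabilities at fixed size and mean degree, with the closed-form
#'   approximation alongside.
#' * `"diversity_vs_index"`: for a battery of networks (complete,
#'   Watts-Strogatz at two rewiring levels, scale-free), simulates the
#'   voter model at per-capita innovation rate `alpha = 1` and compares the
#'   observed long-run diversity with the prediction from the estimated
#'   index.
#' * `"unfollow_corpus"`: evaluates the unfollow intervention for
#'   `h = 1..4` across a Watts-Strogatz corpus and summarizes with
#'   [summarize_intervention_corpus()].
#'
#' All randomness flows from the session RNG: `set.seed()` before calling
#' makes the experiment exactly reproducible.
#'
#' @param experiment one of `"scalefree_scaling"`, `"smallworld_rewiring"`,
#'   `"diversity_vs_index"`, `"unfollow_corpus"`.
#' @param n base network size.
#' @param n_realizations meeting-time realizations per network.
#' @param gammas exponent grid for `"scalefree_scaling"`.
#' @param s_grid rewiring grid for `"smallworld_rewiring"`.
#' @param ws_k mean degree of WS networks.
#' @param sf_kmin minimum degree of scale-free networks.
#' @param corpus_size number of networks for `"unfollow_corpus"`.
#' @param h_values intervention strengths for `"unfollow_corpus"`.
#' @param voter_reps voter replicates for `"diversity_vs_index"`.
#' @return a list with `experiment`, `config`, and experiment-specific
#'   tables (`table`, plus `fit` or `summary` where applicable).
#' @export
run_experiment <- function(experiment = c("scalefree_scaling",
                                          "smallworld_rewiring",
                                          "diversity_vs_index",
                                          "unfollow_corpus"),
                           n = 1000, n_realizations = 10000,
                           gammas = seq(2.1, 2.9, by = 0.1),
                           s_grid = c(0.001, 0.003, 0.01, 0.03, 0.1, 0.3, 1),
                           ws_k = 6, sf_kmin = 4, corpus_size = 20,
                           h_values = 1:4, voter_reps = 20) {
  experiment <- match.arg(experiment)
  config <- list(n = n, n_realizations = n_realizations)
  if (experiment == "scalefree_scaling") {
    rows <- lapply(gammas, function(gamma) {
      g <- suppressMessages(graph_scale_free(n, gamma, sf_kmin))
      est <- estimate_delta(g, n_realizations)
      data.frame(gamma = gamma, n_realized = igraph::vcount(g),
                 delta = est$delta,
                 se = est$std_error / est$n_vertices,
                 n_censored = est$n_censored,
                 bound = scale_free_bound(igraph::vcount(g), gamma)$value)
    })
    tab <- do.call(rbind, rows)
    fit <- fit_scalefree_scaling(tab$gamma, tab$delta, tab$n_realized)
    return(list(experiment = experiment, config = config, table = tab,
                fit = fit))
  }
  if (experiment == "smallworld_rewiring") {
    rows <- lapply(s_grid, function(s) {
      g <- graph_watts_strogatz(n, ws_k, s)
      est <- estimate_delta(g, n_realizations)
      data.frame(s = s, delta = est$delta,
                 se = est$std_error / est$n_vertices,
                 n_censored = est$n_censored,
                 approx = ws_index_approximation(n, ws_k, s)$value)
    })
    return(list(experiment = experiment, config = config,
                table = do.call(rbind, rows)))
  }
  if (experiment == "diversity_vs_index") {
    battery <- list(
      complete = graph_complete(max(100, round(n / 5))),
      ws_low_s = graph_watts_strogatz(max(500, round(n / 2)), ws_k, 0.01),
      ws_high_s = graph_watts_strogatz(max(500, round(n / 2)), ws_k, 0.1),
      scale_free = suppressMessages(
        graph_scale_free(max(500, round(n / 2)), 2.5, sf_kmin))
    )
    rows <- lapply(names(battery), function(nm) {
      g <- battery[[nm]]
      est <- estimate_delta(g, n_realizations)
      traj <- run_voter(g, alpha = 1, n_reps = voter_reps)
      data.frame(network = nm, n = igraph::vcount(g), delta = est$delta,
                 d_infinity = traj$d_infinity,
                 predicted = predicted_diversity(est$delta, 1))
    })
    return(list(experiment = experiment, config = config,
                table = do.call(rbind, rows)))
  }
  # unfollow_corpus
  results <- list()
  rows <- list()
  for (i in seq_len(corpus_size)) {
    s <- exp(stats::runif(1, log(0.01), log(0.3)))
    g <- graph_watts_strogatz(max(100, round(n / 5)), ws_k, s)
    for (h in h_values) {
      res <- evaluate_intervention(g, h, n_realizations)
      results[[length(results) + 1]] <- res
      rows[[length(rows) + 1]] <- data.frame(
        network = sprintf("ws_%02d", i), s = s, h = h,
        delta_before = res$delta_before, delta_after = res$delta_after,
        relative_change = res$relative_change,
        retained_fraction = res$retained_fraction,
        discarded = res$discarded)
    }
  }
  summary <- summarize_intervention_corpus(results)
  list(experiment = experiment, config = config,
       table = do.call(rbind, rows), summary = summary)
}
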