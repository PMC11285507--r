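#' "Don't follow leaders": drop links to the most connected neighbours
#'
#' Each vertex marks its edges to its `h` highest-degree neighbours (degrees
#' taken in the original graph; ties broken at random; vertices with at most
#' `h` neighbours mark all of them). The union of marked edges is deleted in
#' one simultaneous batch — an undirected edge disappears if either endpoint
#' marks it — and the largest connected component of the residue is
#' returned. `h = 0` is the identity.
#'
#' @param g a connected undirected igraph.
#' @param h number of top-degree neighbours each vertex unfollows.
#' @return an igraph (largest connected component of the residue; a single
#'   vertex when no edges survive).
#' @export
#' @examples
#' g <- igraph::make_star(5, mode = "undirected")
#' igraph::vcount(unfollow_top(g, 1)) # 1: every leaf cuts the hub
unfollow_top <- function(g, h) {
  h <- assert_count(h, "h", min = 0)
  if (h == 0) return(g)
  degs <- igraph::degree(g)
  el <- igraph::as_edgelist(g, names = FALSE)
  n <- igraph::vcount(g)
  # neighbours and incident edge ids per vertex
  inc <- igraph::incident_edges(g, igraph::V(g))
  marked <- logical(igraph::ecount(g))
  for (v in seq_len(n)) {
    eids <- as.integer(inc[[v]])
    if (length(eids) == 0) next
    other <- ifelse(el[eids, 1] == v, el[eids, 2], el[eids, 1])
    # highest original degree first, random tie order
    ord <- order(-degs[other], stats::runif(length(other)))
    marked[eids[head(ord, h)]] <- TRUE
  }
  residue <- igraph::delete_edges(g, which(marked))
  largest_component(residue)
}

#' Evaluate the unfollow intervention on one network
#'
#' Estimates the structural diversity index before and after
#' [unfollow_top()]. The post-intervention index is computed on the largest
#' connected component of the residue. Networks whose residue retains fewer
#' than a quarter of the vertices are flagged `discarded = "size"` (too
#' disrupted for a meaningful comparison); for these no index is estimated
#' and `delta_before`, `delta_after` and `relative_change` are `NA`.
#'
#' @param g a connected undirected igraph.
#' @param h number of top-degree neighbours each vertex unfollows.
#' @param n_realizations,smax_multiplier passed to [estimate_delta()].
#' @return an object of class `intervention_result`: a list with `h`,
#'   `delta_before`, `delta_after`, `se_before`, `se_after`,
#'   `relative_change`, `retained_fraction`, `discarded` (`"size"` or
#'   `"none"`; the corpus-level outlier flag is applied by
#'   [summarize_intervention_corpus()]).
#' @export
evaluate_intervention <- function(g, h, n_realizations = 10000,
                                  smax_multiplier = 100) {
  assert_connected(g, "evaluate_intervention()")
  gh <- unfollow_top(g, h)
  retained <- igraph::vcount(gh) / igraph::vcount(g)
  discarded <- if (retained < 0.25) "size" else "none"
  delta_before <- NA_real_
  se_before <- NA_real_
  delta_after <- NA_real_
  se_after <- NA_real_
  rel <- NA_real_
  if (discarded == "none") {
    before <- estimate_delta(g, n_realizations, smax_multiplier)
    delta_before <- before$delta
    se_before <- before$std_error / before$n_vertices
    if (h == 0) {
      delta_after <- delta_before
      se_after <- se_before
      rel <- 0
    } else {
      after <- estimate_delta(gh, n_realizations, smax_multiplier)
      delta_after <- after$delta
      se_after <- after$std_error / after$n_vertices
      rel <- (delta_after - delta_before) / delta_before
    }
  }
  structure(list(
    h = h,
    delta_before = delta_before,
    delta_after = delta_after,
    se_before = se_before,
    se_after = se_after,
    relative_change = rel,
    retained_fraction = retained,
    discarded = discarded
  ), class = "intervention_result")
}

#' @export
print.intervention_result <- function(x, ...) {
  cat(sprintf("Unfollow intervention (h = %d)\n", x$h))
  cat(sprintf("  delta %.4f -> %s, retained %.2f%%",
              x$delta_before,
              if (is.na(x$delta_after)) "NA" else sprintf("%.4f", x$delta_after),
              100 * x$retained_fraction))
  if (!is.na(x$relative_change)) {
    cat(sprintf(", relative change %+.2f%%", 100 * x$relative_change))
  }
  cat(sprintf(" [discarded: %s]\n", x$discarded))
  invisible(x)
}

#' Summarize an intervention corpus
#'
#' Pools [evaluate_intervention()] results over networks and `h` values.
#' Per `h`, size-discarded results are dropped first, then results whose
#' relative change deviates more than one standard deviation from the mean
#' relative change of the size-filtered sample for that `h` are flagged as
#' outliers and dropped. An ordinary least-squares line of relative change
#' on `h` is fitted through the retained points.
#'
#' @param results a list of `intervention_result` objects covering at least
#'   two distinct `h` values after filtering.
#' @return a list with `table` (one row per result with a `kept` flag and
#'   discard reason), `per_h` (mean/sd/counts per `h`), `slope`,
#'   `intercept`, `r_squared`, and `n_discarded` by reason.
#' @export
summarize_intervention_corpus <- function(results) {
  stopifnot(length(results) > 0)
  tab <- data.frame(
    h = vapply(results, `[[`, 1, "h"),
    relative_change = vapply(results, `[[`, 1, "relative_change"),
    retained_fraction = vapply(results, `[[`, 1, "retained_fraction"),
    discarded = vapply(results, `[[`, "", "discarded"),
    stringsAsFactors = FALSE
  )
  for (hv in unique(tab$h)) {
    idx <- which(tab$h == hv & tab$discarded == "none")
    if (length(idx) < 2) next
    rc <- tab$relative_change[idx]
    # small epsilon so exact 1-s.d. float ties are not flagged
    out <- abs(rc - mean(rc)) > sd(rc) + 1e-12
    tab$discarded[idx[out]] <- "outlier"
  }
  tab$kept <- tab$discarded == "none"
  kept <- tab[tab$kept, ]
  if (length(unique(kept$h)) < 2) {
    stop("fewer than 2 distinct h values survive the filters", call. = FALSE)
  }
  fit <- lm(relative_change ~ h, data = kept)
  per_h <- do.call(rbind, lapply(split(kept, kept$h), function(d) {
    data.frame(h = d$h[1], n = nrow(d), mean = mean(d$relative_change),
               sd = if (nrow(d) > 1) sd(d$relative_change) else NA_real_)
  }))
  rownames(per_h) <- NULL
  list(table = tab, per_h = per_h,
       slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r_squared = summary(fit)$r.squared,
       n_discarded = c(size = sum(tab$discarded == "size"),
                       outlier = sum(tab$discarded == "outlier")))
}
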