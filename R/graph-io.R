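#' Read an undirected graph from a plain-text edge list
#'
#' One edge per line, two whitespace- or comma-separated tokens; `#` starts a
#' comment. Arbitrary string tokens are mapped to contiguous internal vertex
#' ids in first-seen order; the original tokens are kept as vertex names.
#' Self-loops and duplicate edges are dropped with a warning (random walks and
#' voter updates assume a neighbour is never the vertex itself).
#'
#' @param path path to an edge-list file, or a connection.
#' @return an undirected [igraph::igraph] with vertex attribute `name`.
#' @seealso [write_edgelist()]
#' @export
#' @examples
#' f <- tempfile()
#' writeLines(c("a b", "b c", "# comment"), f)
#' g <- read_edgelist(f)
#' igraph::vcount(g) # 3
read_edgelist <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  keep <- which(trimws(lines) != "")
  if (length(keep) == 0) stop("empty edge list: ", path, call. = FALSE)
  toks <- strsplit(trimws(lines[keep]), "[,[:space:]]+")
  bad <- which(lengths(toks) < 2)
  if (length(bad) > 0) {
    stop("malformed edge list line ", keep[bad[1]], ": fewer than 2 tokens",
         call. = FALSE)
  }
  from <- vapply(toks, `[`, character(1), 1)
  to <- vapply(toks, `[`, character(1), 2)
  labels <- unique(c(rbind(from, to)))
  u <- match(from, labels)
  v <- match(to, labels)
  self <- u == v
  if (any(self)) {
    warning(sum(self), " self-loop(s) dropped", call. = FALSE)
    u <- u[!self]
    v <- v[!self]
  }
  key <- paste(pmin(u, v), pmax(u, v))
  dup <- duplicated(key)
  if (any(dup)) {
    warning(sum(dup), " duplicate edge(s) dropped", call. = FALSE)
    u <- u[!dup]
    v <- v[!dup]
  }
  if (length(u) == 0) stop("no edges left after cleaning: ", path, call. = FALSE)
  g <- igraph::make_empty_graph(n = length(labels), directed = FALSE)
  g <- igraph::add_edges(g, rbind(u, v))
  igraph::V(g)$name <- labels
  g
}

#' Write a graph as a plain-text edge list
#'
#' Emits one edge per line using the original vertex labels (vertex names, or
#' internal ids if unnamed). `read_edgelist(write_edgelist(g, f))` recovers
#' the same edge set.
#'
#' @param g an undirected igraph.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_edgelist <- function(g, path) {
  if (igraph::ecount(g) == 0) stop("graph has no edges", call. = FALSE)
  el <- igraph::as_edgelist(g, names = igraph::is_named(g))
  writeLines(paste(el[, 1], el[, 2]), path)
  invisible(path)
}

#' Largest connected component
#'
#' Returns the induced subgraph on the largest connected component, with
#' vertex ids remapped to be contiguous and names preserved. Ties between
#' equal-size components are broken in favour of the component containing the
#' earliest-seen (smallest internal id) vertex. Idempotent.
#'
#' @param g an undirected igraph.
#' @return an igraph.
#' @export
largest_component <- function(g) {
  comp <- igraph::components(g)
  biggest <- which(comp$csize == max(comp$csize))
  if (length(biggest) > 1) {
    first <- vapply(biggest, function(k) min(which(comp$membership == k)), 1)
    biggest <- biggest[which.min(first)]
  }
  igraph::induced_subgraph(g, which(comp$membership == biggest))
}
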