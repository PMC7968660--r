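#' Erdos-Renyi G(N, L) random network
#'
#' Draws exactly `n_links` distinct unordered node pairs uniformly at
#' random among `n_nodes` nodes — every possible link is equally likely, so
#' the null shares the empirical network's node and link counts while
#' erasing all structure.
#'
#' @param n_nodes Number of nodes.
#' @param n_links Number of links; `0 <= n_links <= n_nodes(n_nodes-1)/2`.
#' @param seed Integer seed; `NULL` uses the current RNG stream.
#' @return igraph graph with exactly `n_links` edges.
#' @export
er_random_network <- function(n_nodes, n_links, seed = NULL) {
  max_links <- n_nodes * (n_nodes - 1) / 2
  if (n_links < 0 || n_links > max_links) {
    fail("n_links must lie in [0, %d] for %d nodes", max_links, n_nodes)
  }
  with_seed(seed, igraph::sample_gnm(n_nodes, n_links, directed = FALSE))
}

#' Random-network null summary
#'
#' Generates `n_reps` G(N, L) networks at the empirical node and link
#' counts and summarizes the same topology metrics used for the empirical
#' network — average path distance, average clustering coefficient and
#' greedy modularity — as means and standard deviations across replicates.
#'
#' @param n_nodes,n_links Empirical node and link counts.
#' @param n_reps Number of null replicates (>= 2; default 100).
#' @param seed Integer seed for the whole replicate stream.
#' @return List of class `"null_summary"` with `n_reps`, `n_nodes`,
#'   `n_links`, `mean` and `sd` (each a named vector over the three
#'   metrics), and `replicates` (data.frame of per-replicate values).
#' @export
null_summary <- function(n_nodes, n_links, n_reps = 100, seed = NULL) {
  if (n_reps < 2L) fail("n_reps must be at least 2")
  if (n_links < 1L) fail("need at least one link to summarize topology")
  vals <- with_seed(seed, {
    t(vapply(seq_len(n_reps), function(i) {
      g <- igraph::sample_gnm(n_nodes, n_links, directed = FALSE)
      c(avg_path_distance = suppressMessages(avg_path_distance(g)),
        avg_clustering_coefficient = avg_clustering(g),
        modularity = detect_modules(g)$modularity)
    }, numeric(3)))
  })
  structure(list(
    n_reps = n_reps, n_nodes = n_nodes, n_links = n_links,
    mean = colMeans(vals),
    sd = apply(vals, 2L, stats::sd),
    replicates = as.data.frame(vals)
  ), class = "null_summary")
}

#' @export
print.null_summary <- function(x, ...) {
  cat(sprintf("G(N = %d, L = %d) null, %d replicates\n",
              x$n_nodes, x$n_links, x$n_reps))
  for (m in names(x$mean)) {
    cat(sprintf("  %s: %.4f (sd %.4f)\n", m, x$mean[[m]], x$sd[[m]]))
  }
  invisible(x)
}
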