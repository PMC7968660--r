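#' Build a signed co-occurrence network from a similarity matrix
#'
#' Draws an undirected edge between taxa i and j iff `|rho[i, j]| > st`
#' (strictly larger than the similarity threshold); the edge keeps the rho
#' value and its sign.  Nodes left without any edge are removed, so the
#' node count of the resulting network can vary between datasets sharing a
#' taxon pool.  Community detection and all topology metrics operate on the
#' unsigned skeleton; the sign is carried per edge for reporting.
#'
#' @param sim Symmetric Spearman matrix from [spearman_matrix()].
#' @param st Similarity threshold in (0, 1); default 0.6.
#' @param taxonomy Optional named vector (taxon -> phylum) stored as a
#'   `phylum` vertex attribute.
#' @param abundance Optional named numeric vector (taxon -> mean abundance)
#'   stored as an `abundance` vertex attribute.
#' @return An [igraph::igraph] graph with edge attributes `rho` and `sign`
#'   ("+"/"-") and graph attribute `st`.
#' @export
build_network <- function(sim, st = 0.6, taxonomy = NULL, abundance = NULL) {
  if (length(st) != 1L || !is.finite(st) || st <= 0 || st >= 1) {
    fail("st must lie strictly between 0 and 1")
  }
  if (!isSymmetric(unname(sim))) fail("similarity matrix must be symmetric")
  ids <- rownames(sim)
  hit <- abs(sim) > st
  diag(hit) <- FALSE
  idx <- which(hit & upper.tri(hit), arr.ind = TRUE)
  edges <- data.frame(
    from = ids[idx[, 1L]],
    to = ids[idx[, 2L]],
    rho = sim[idx],
    sign = ifelse(sim[idx] > 0, "+", "-"),
    stringsAsFactors = FALSE
  )
  vertices <- data.frame(name = ids, stringsAsFactors = FALSE)
  if (!is.null(taxonomy)) vertices$phylum <- unname(taxonomy[ids])
  if (!is.null(abundance)) vertices$abundance <- unname(abundance[ids])
  g <- igraph::graph_from_data_frame(edges, directed = FALSE, vertices = vertices)
  g <- igraph::delete_vertices(g, which(igraph::degree(g) == 0L))
  g <- igraph::set_graph_attr(g, "st", st)
  g
}

.require_edges <- function(net) {
  if (igraph::ecount(net) < 1L) fail("network has no edges")
}

#' Percentages of positive and negative links
#'
#' @param net Network from [build_network()] (needs the `sign` edge
#'   attribute and at least one edge).
#' @return Named numeric vector `c(pct_positive, pct_negative)`, summing
#'   to 100.
#' @export
link_sign_fractions <- function(net) {
  .require_edges(net)
  s <- igraph::E(net)$sign
  pos <- 100 * sum(s == "+") / length(s)
  c(pct_positive = pos, pct_negative = 100 - pos)
}

#' Average connectivity (mean degree)
#'
#' `2 * links / nodes`, equal to the mean of the per-node degrees.
#'
#' @param net igraph graph with at least one node.
#' @return Numeric scalar.
#' @export
avg_connectivity <- function(net) {
  if (igraph::vcount(net) < 1L) fail("network has no nodes")
  2 * igraph::ecount(net) / igraph::vcount(net)
}

#' Average path distance
#'
#' Mean unweighted shortest-path length over all unordered node pairs that
#' lie in the same connected component; pairs in different components are
#' excluded (and noted via a message when any exist).
#'
#' @param net igraph graph with at least one edge.
#' @return Numeric scalar >= 1.
#' @export
avg_path_distance <- function(net) {
  .require_edges(net)
  if (!igraph::is_connected(net)) {
    comp <- igraph::components(net)
    n <- igraph::vcount(net)
    unreachable <- (n * (n - 1) / 2) - sum(choose(comp$csize, 2))
    message(sprintf("network is disconnected; %d node pair(s) excluded from path average",
                    unreachable))
  }
  igraph::mean_distance(net, directed = FALSE, unconnected = TRUE)
}

#' Average clustering coefficient
#'
#' Mean over nodes of the local clustering coefficient
#' `C_i = 2 e_i / (k_i (k_i - 1))`; nodes of degree < 2 contribute 0.
#'
#' @param net igraph graph with at least one node.
#' @return Numeric scalar in \[0, 1\].
#' @export
avg_clustering <- function(net) {
  if (igraph::vcount(net) < 1L) fail("network has no nodes")
  igraph::transitivity(net, type = "localaverage", isolates = "zero")
}

#' Greedy modularity maximization
#'
#' Agglomerative (fast-greedy) modularity optimization on the unsigned,
#' unweighted skeleton, merging communities while modularity
#' `Q = sum_m [ l_m / L - (d_m / 2L)^2 ]` improves.  Deterministic for a
#' given graph.
#'
#' @param net igraph graph with at least one edge.
#' @return List of class `"module_partition"`: `membership` (named integer
#'   vector), `modularity` (Q of the returned partition), `n_modules`.
#' @export
detect_modules <- function(net) {
  .require_edges(net)
  cm <- igraph::cluster_fast_greedy(net, weights = NULL)
  # cut the merge tree at the step with maximal modularity ourselves: the
  # cut igraph picks can land one step early when the optimum is a
  # floating-point-noise zero (e.g. a single clique)
  best <- which.max(cm$modularity)
  memb <- igraph::cut_at(cm, no = igraph::vcount(net) - (best - 1L))
  memb <- stats::setNames(as.integer(memb), igraph::V(net)$name)
  structure(list(
    membership = memb,
    modularity = igraph::modularity(net, memb),
    n_modules = length(unique(memb))
  ), class = "module_partition")
}

#' @export
print.module_partition <- function(x, ...) {
  cat(sprintf("module_partition: %d modules, Q = %.4f\n", x$n_modules, x$modularity))
  invisible(x)
}

#' Topology report for one co-occurrence network
#'
#' Assembles the standard metric set: node and link counts, link-sign
#' percentages, average connectivity, average path distance, average
#' clustering coefficient, and greedy modularity.
#'
#' @param net Network from [build_network()] with at least one edge.
#' @param partition Optional precomputed [detect_modules()] result.
#' @return List of class `"network_report"` with the metrics and the module
#'   partition.
#' @export
network_report <- function(net, partition = NULL) {
  .require_edges(net)
  if (is.null(partition)) partition <- detect_modules(net)
  fr <- link_sign_fractions(net)
  structure(list(
    total_nodes = igraph::vcount(net),
    total_links = igraph::ecount(net),
    pct_positive_links = unname(fr["pct_positive"]),
    pct_negative_links = unname(fr["pct_negative"]),
    avg_connectivity = avg_connectivity(net),
    avg_path_distance = avg_path_distance(net),
    avg_clustering_coefficient = avg_clustering(net),
    modularity = partition$modularity,
    partition = partition
  ), class = "network_report")
}

#' @export
print.network_report <- function(x, ...) {
  cat("co-occurrence network report\n")
  cat(sprintf("  nodes %d, links %d (%.2f%% +, %.2f%% -)\n",
              x$total_nodes, x$total_links,
              x$pct_positive_links, x$pct_negative_links))
  cat(sprintf("  avg connectivity %.4f, path distance %.4f, clustering %.4f\n",
              x$avg_connectivity, x$avg_path_distance,
              x$avg_clustering_coefficient))
  cat(sprintf("  modularity %.4f (%d modules)\n",
              x$modularity, x$partition$n_modules))
  invisible(x)
}

#' Export a network as a signed edge-list TSV
#'
#' Columns: `from`, `to`, `rho`, `sign`.
#'
#' @param net Network from [build_network()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(net, path) {
  el <- igraph::as_edgelist(net)
  df <- data.frame(from = el[, 1L], to = el[, 2L],
                   rho = igraph::E(net)$rho, sign = igraph::E(net)$sign)
  write_tsv(df, path)
}

#' Export a network as GraphML
#'
#' @param net igraph graph.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_graphml <- function(net, path) {
  igraph::write_graph(net, path, format = "graphml")
  invisible(path)
}
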