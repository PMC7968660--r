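#' Within-module degree z-score (Zi)
#'
#' For node i in module m, `Zi = (kappa_i - mean_m kappa) / sd_m kappa`,
#' where `kappa_i` counts i's links to other members of its own module and
#' the mean/sd run over the members of m (population sd).  Modules whose
#' members all have the same within-module degree (sd = 0) get Zi = 0.
#'
#' @param net igraph graph.
#' @param membership Named integer vector assigning every node of `net` to
#'   a module (e.g. `detect_modules(net)$membership`).
#' @return Named numeric vector of Zi values.
#' @export
within_module_degree_z <- function(net, membership) {
  ids <- igraph::V(net)$name
  if (!all(ids %in% names(membership))) {
    fail("node(s) missing from partition: %s",
         paste(setdiff(ids, names(membership)), collapse = ", "))
  }
  m <- membership[ids]
  A <- igraph::as_adjacency_matrix(net, sparse = FALSE)
  kappa <- vapply(seq_along(ids), function(i) sum(A[i, m == m[i]]), numeric(1))
  z <- numeric(length(ids))
  for (mod in unique(m)) {
    sel <- which(m == mod)
    mu <- mean(kappa[sel])
    s <- sqrt(mean((kappa[sel] - mu)^2))
    z[sel] <- if (s == 0) 0 else (kappa[sel] - mu) / s
  }
  stats::setNames(z, ids)
}

#' Among-module participation coefficient (Pi)
#'
#' `Pi = 1 - sum_t (k_it / k_i)^2` over modules t, with `k_it` the number
#' of links from node i into module t and `k_i` its total degree.  Pi = 0
#' when all links stay inside the node's own module; values approach
#' `1 - 1/k_i` when links spread evenly.
#'
#' @inheritParams within_module_degree_z
#' @return Named numeric vector of Pi values in \[0, 1\].
#' @export
participation_coefficient <- function(net, membership) {
  ids <- igraph::V(net)$name
  if (!all(ids %in% names(membership))) {
    fail("node(s) missing from partition: %s",
         paste(setdiff(ids, names(membership)), collapse = ", "))
  }
  deg <- igraph::degree(net)
  if (any(deg == 0L)) {
    fail("isolated node(s) have no participation coefficient: %s",
         paste(ids[deg == 0L], collapse = ", "))
  }
  m <- membership[ids]
  A <- igraph::as_adjacency_matrix(net, sparse = FALSE)
  mods <- sort(unique(as.integer(m)))
  ind <- outer(as.integer(m), mods, "==") + 0  # nodes x modules indicator
  k_it <- A %*% ind
  pi_val <- 1 - rowSums((k_it / deg)^2)
  stats::setNames(as.numeric(pi_val), ids)
}

#' Classify node roles on the Zi-Pi plane
#'
#' The standard four-region scheme: peripheral (`Zi < z_thresh`,
#' `Pi <= p_thresh`), connector (`Zi < z_thresh`, `Pi > p_thresh`),
#' module hub (`Zi >= z_thresh`, `Pi <= p_thresh`) and network hub
#' (`Zi >= z_thresh`, `Pi > p_thresh`).  Default thresholds 2.5 and 0.62.
#' Every (Zi, Pi) point, including boundary values, falls in exactly one
#' category; connectors and hubs are the usual keystone candidates.
#'
#' @param zi,pi_val Numeric vectors of Zi and Pi values (recycled).
#' @param z_thresh,p_thresh Role thresholds (default 2.5 and 0.62).
#' @return Factor with levels `peripheral`, `connector`, `module_hub`,
#'   `network_hub`.
#' @export
classify_role <- function(zi, pi_val, z_thresh = 2.5, p_thresh = 0.62) {
  if (z_thresh <= 0 || p_thresh <= 0) fail("thresholds must be positive")
  hub <- zi >= z_thresh
  spread <- pi_val > p_thresh
  out <- ifelse(hub,
                ifelse(spread, "network_hub", "module_hub"),
                ifelse(spread, "connector", "peripheral"))
  factor(out, levels = c("peripheral", "connector", "module_hub", "network_hub"))
}

#' Node role table (the Zi-Pi scatter as data)
#'
#' @param net Network from [build_network()].
#' @param partition Optional [detect_modules()] result or a named
#'   membership vector (computed by [detect_modules()] if missing).
#' @param z_thresh,p_thresh Role thresholds passed to [classify_role()].
#' @return data.frame with `node`, `phylum` (if the network carries it),
#'   `module`, `Zi`, `Pi`, `category`.
#' @export
node_role_table <- function(net, partition = NULL, z_thresh = 2.5, p_thresh = 0.62) {
  if (is.null(partition)) partition <- detect_modules(net)
  memb <- if (inherits(partition, "module_partition")) {
    partition$membership
  } else partition
  zi <- within_module_degree_z(net, memb)
  pv <- participation_coefficient(net, memb)
  ids <- igraph::V(net)$name
  out <- data.frame(
    node = ids,
    module = as.integer(memb[ids]),
    Zi = unname(zi[ids]),
    Pi = unname(pv[ids]),
    category = classify_role(unname(zi[ids]), unname(pv[ids]),
                             z_thresh = z_thresh, p_thresh = p_thresh),
    row.names = NULL
  )
  if ("phylum" %in% igraph::vertex_attr_names(net)) {
    out <- cbind(out[1L], phylum = igraph::V(net)$phylum, out[-1L])
  }
  out
}
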