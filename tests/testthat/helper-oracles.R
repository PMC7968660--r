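# Brute-force oracles and fixture builders, independent of the package's
# implementation paths.

rand_count_table <- function(n_taxa = 6, n_samples = 4) {
  m <- matrix(rpois(n_taxa * n_samples, lambda = 20), n_taxa, n_samples,
              dimnames = list(sprintf("t%02d", seq_len(n_taxa)),
                              sprintf("s%02d", seq_len(n_samples))))
  count_table(m)
}

# Spearman rho by hand: mid-ranks, then the Pearson formula written out.
spearman_oracle <- function(x, y) {
  rx <- rank(x)
  ry <- rank(y)
  dx <- rx - mean(rx)
  dy <- ry - mean(ry)
  sum(dx * dy) / sqrt(sum(dx^2) * sum(dy^2))
}

# Random simple undirected graph as a named adjacency matrix.
rand_adjacency <- function(n, p = 0.4) {
  A <- matrix(0L, n, n)
  A[upper.tri(A)] <- as.integer(runif(n * (n - 1) / 2) < p)
  A <- A + t(A)
  dimnames(A) <- list(sprintf("v%d", seq_len(n)), sprintf("v%d", seq_len(n)))
  A
}

graph_from_adj <- function(A) {
  igraph::graph_from_adjacency_matrix(A, mode = "undirected")
}

# All-pairs shortest paths by repeated BFS over the adjacency matrix.
path_oracle <- function(A) {
  n <- nrow(A)
  total <- 0; pairs <- 0
  for (s in seq_len(n)) {
    dist <- rep(Inf, n); dist[s] <- 0
    frontier <- s
    d <- 0
    while (length(frontier)) {
      d <- d + 1
      nxt <- integer(0)
      for (v in frontier) {
        for (w in which(A[v, ] > 0)) {
          if (dist[w] > d) { dist[w] <- d; nxt <- c(nxt, w) }
        }
      }
      frontier <- unique(nxt)
    }
    reach <- which(is.finite(dist) & seq_len(n) > s)
    total <- total + sum(dist[reach])
    pairs <- pairs + length(reach)
  }
  if (pairs == 0) NaN else total / pairs
}

# Mean local clustering by exhaustive neighbour-pair counting.
clustering_oracle <- function(A) {
  n <- nrow(A)
  cc <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(A[i, ] > 0)
    k <- length(nb)
    if (k < 2) { cc[i] <- 0; next }
    e <- sum(A[nb, nb]) / 2
    cc[i] <- 2 * e / (k * (k - 1))
  }
  mean(cc)
}

# Modularity of a given partition, straight from the definition.
modularity_oracle <- function(A, memb) {
  L <- sum(A) / 2
  deg <- rowSums(A)
  Q <- 0
  for (m in unique(memb)) {
    sel <- memb == m
    Q <- Q + sum(A[sel, sel]) / 2 / L - (sum(deg[sel]) / (2 * L))^2
  }
  Q
}

# All set partitions of n elements (restricted growth strings).
all_partitions <- function(n) {
  res <- list()
  rec <- function(prefix, maxv) {
    if (length(prefix) == n) { res[[length(res) + 1L]] <<- prefix; return(invisible()) }
    for (v in seq_len(maxv + 1L)) rec(c(prefix, v), max(maxv, v))
  }
  rec(integer(0), 0L)
  res
}

max_modularity_oracle <- function(A) {
  parts <- all_partitions(nrow(A))
  max(vapply(parts, function(p) modularity_oracle(A, p), numeric(1)))
}

# Zi / Pi by direct edge counting (sample sd replaced by population sd for
# Zi, as the within-module z-score is defined over the module's members).
zi_oracle <- function(A, memb) {
  n <- nrow(A)
  kappa <- vapply(seq_len(n), function(i) sum(A[i, memb == memb[i]]), numeric(1))
  z <- numeric(n)
  for (m in unique(memb)) {
    sel <- memb == m
    mu <- mean(kappa[sel])
    s <- sqrt(sum((kappa[sel] - mu)^2) / sum(sel))
    z[sel] <- if (s == 0) 0 else (kappa[sel] - mu) / s
  }
  z
}

pi_oracle <- function(A, memb) {
  n <- nrow(A)
  vapply(seq_len(n), function(i) {
    k <- sum(A[i, ])
    if (k == 0) return(NA_real_)
    1 - sum(vapply(unique(memb), function(m) (sum(A[i, memb == m]) / k)^2,
                   numeric(1)))
  }, numeric(1))
}

# Canonical unordered-pair keys for edge-set comparisons.
pair_keys <- function(a, b) paste(pmin(a, b), pmax(a, b))

graph_edge_keys <- function(net) {
  el <- igraph::as_edgelist(net)
  if (nrow(el) == 0) return(character(0))
  pair_keys(el[, 1], el[, 2])
}
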