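# Network construction and topology metrics.

test_that("edges require |rho| strictly above St and keep their sign", {
  rho <- diag(3)
  dimnames(rho) <- list(letters[1:3], letters[1:3])
  rho["a", "b"] <- rho["b", "a"] <- 0.7
  rho["a", "c"] <- rho["c", "a"] <- -0.65
  rho["b", "c"] <- rho["c", "b"] <- 0.6      # exactly St: no edge
  net <- build_network(rho, st = 0.6)
  keys <- graph_edge_keys(net)
  expect_setequal(keys, c("a b", "a c"))
  signs <- setNames(igraph::E(net)$sign, keys)
  expect_equal(unname(signs["a b"]), "+")
  expect_equal(unname(signs["a c"]), "-")
  expect_error(build_network(rho, st = 1.2), "between 0 and 1")
})

test_that("isolated nodes are dropped and raising St only removes edges", {
  set.seed(42)
  x <- matrix(rnorm(80), 8, 10,
              dimnames = list(paste0("t", 1:8), paste0("s", 1:10)))
  rho <- spearman_matrix(x)
  net4 <- build_network(rho, st = 0.4)
  expect_true(all(igraph::degree(net4) > 0))
  for (st in c(0.5, 0.7, 0.9)) {
    expect_true(all(graph_edge_keys(build_network(rho, st = st)) %in%
                      graph_edge_keys(build_network(rho, st = st - 0.1))))
  }
  st_max <- max(abs(rho[upper.tri(rho)]))
  if (st_max < 1) {
    expect_equal(igraph::ecount(build_network(rho, st = st_max)), 0)
  }
})

test_that("closed-form metric values on canonical small graphs", {
  A <- matrix(1L, 3, 3) - diag(1L, 3)
  dimnames(A) <- list(letters[1:3], letters[1:3])
  tri <- graph_from_adj(A)
  expect_equal(avg_connectivity(tri), 2)
  expect_equal(avg_path_distance(tri), 1)
  expect_equal(avg_clustering(tri), 1)

  star5 <- igraph::make_star(5, mode = "undirected", center = 1)
  expect_equal(avg_connectivity(star5), 1.6)
  star4 <- igraph::make_star(4, mode = "undirected", center = 1)
  expect_equal(avg_clustering(star4), 0)

  path3 <- igraph::graph_from_literal(a - b - c)
  expect_equal(avg_path_distance(path3), 4 / 3)
})

test_that("topology metrics match exhaustive-enumeration oracles on random graphs", {
  set.seed(55)
  tested <- 0
  while (tested < 100) {
    n <- sample(4:8, 1)
    A <- rand_adjacency(n, p = runif(1, 0.25, 0.8))
    if (sum(A) == 0) next
    tested <- tested + 1
    g <- graph_from_adj(A)
    expect_equal(avg_connectivity(g), mean(rowSums(A)), tolerance = 1e-12)
    expect_equal(avg_clustering(g), clustering_oracle(A), tolerance = 1e-12)
    expect_equal(suppressMessages(avg_path_distance(g)), path_oracle(A),
                 tolerance = 1e-12)
  }
})

test_that("link-sign fractions come from exhaustive edge counts", {
  rho <- diag(5)
  dimnames(rho) <- list(letters[1:5], letters[1:5])
  rho["a", "b"] <- rho["b", "a"] <- 0.9
  rho["a", "c"] <- rho["c", "a"] <- 0.8
  rho["b", "c"] <- rho["c", "b"] <- 0.7
  rho["d", "e"] <- rho["e", "d"] <- -0.9
  net <- build_network(rho, st = 0.6)
  fr <- link_sign_fractions(net)
  expect_equal(unname(fr), c(75, 25))
  expect_equal(sum(fr), 100)

  rho["d", "e"] <- rho["e", "d"] <- 0.9
  fr2 <- link_sign_fractions(build_network(rho, st = 0.6))
  expect_equal(unname(fr2), c(100, 0))

  set.seed(66)
  x <- matrix(rnorm(60), 6, 10,
              dimnames = list(paste0("t", 1:6), paste0("s", 1:10)))
  net3 <- build_network(spearman_matrix(x), st = 0.3)
  fr3 <- link_sign_fractions(net3)
  rhov <- igraph::E(net3)$rho
  expect_equal(unname(fr3["pct_positive"]), 100 * sum(rhov > 0) / length(rhov))
})

test_that("greedy modularity is bounded by the brute-force optimum", {
  # two triangles joined by a bridge: known optimum 5/14
  A <- matrix(0L, 6, 6, dimnames = list(letters[1:6], letters[1:6]))
  for (e in list(c(1, 2), c(1, 3), c(2, 3), c(4, 5), c(4, 6), c(5, 6), c(3, 4))) {
    A[e[1], e[2]] <- A[e[2], e[1]] <- 1L
  }
  g <- graph_from_adj(A)
  part <- detect_modules(g)
  expect_equal(part$modularity, 5 / 14, tolerance = 1e-12)
  expect_equal(part$modularity, max_modularity_oracle(A), tolerance = 1e-12)
  expect_equal(part$n_modules, 2)
  # the two triangles are the two modules
  memb <- part$membership
  expect_equal(length(unique(memb[c("a", "b", "c")])), 1)
  expect_equal(length(unique(memb[c("d", "e", "f")])), 1)
  expect_false(memb[["a"]] == memb[["d"]])

  # single clique: one module, Q = 0
  K <- matrix(1L, 5, 5) - diag(1L, 5)
  dimnames(K) <- list(letters[1:5], letters[1:5])
  pK <- detect_modules(graph_from_adj(K))
  expect_equal(pK$n_modules, 1)
  expect_equal(pK$modularity, 0)

  set.seed(88)
  tested <- 0
  while (tested < 30) {
    n <- sample(4:7, 1)
    A <- rand_adjacency(n, p = runif(1, 0.3, 0.8))
    if (sum(A) == 0) next
    tested <- tested + 1
    p <- detect_modules(graph_from_adj(A))
    expect_gte(p$modularity, 0 - 1e-12)   # never worse than one module
    expect_lte(p$modularity, max_modularity_oracle(A) + 1e-12)
    # reported Q is the Q of the reported partition
    expect_equal(p$modularity,
                 modularity_oracle(A, p$membership[rownames(A)]),
                 tolerance = 1e-12)
  }
})

test_that("network report assembles all metrics consistently", {
  set.seed(10)
  x <- matrix(rnorm(120), 12, 10,
              dimnames = list(paste0("t", 1:12), paste0("s", 1:10)))
  net <- build_network(spearman_matrix(x), st = 0.5)
  rep <- suppressMessages(network_report(net))
  expect_equal(rep$total_nodes, igraph::vcount(net))
  expect_equal(rep$total_links, igraph::ecount(net))
  expect_equal(rep$pct_positive_links + rep$pct_negative_links, 100)
  expect_equal(rep$avg_connectivity, 2 * rep$total_links / rep$total_nodes)
  el_path <- withr::local_tempfile(fileext = ".tsv")
  write_edge_list(net, el_path)
  el <- read.delim(el_path)
  expect_equal(nrow(el), rep$total_links)
  gml <- withr::local_tempfile(fileext = ".graphml")
  write_graphml(net, gml)
  back <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::ecount(back), rep$total_links)
})
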