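# Zi-Pi node roles.

# two five-node star modules joined by one cross edge (b2-a2)
two_star_graph <- function() {
  A <- matrix(0L, 10, 10)
  ids <- c(paste0("a", 1:5), paste0("b", 1:5))
  dimnames(A) <- list(ids, ids)
  for (k in 2:5) {
    A["a1", paste0("a", k)] <- A[paste0("a", k), "a1"] <- 1L
    A["b1", paste0("b", k)] <- A[paste0("b", k), "b1"] <- 1L
  }
  A["a2", "b2"] <- A["b2", "a2"] <- 1L
  A
}

two_star_membership <- function() {
  setNames(rep(1:2, each = 5), c(paste0("a", 1:5), paste0("b", 1:5)))
}

test_that("within-module degree z-score follows the population z formula", {
  A <- two_star_graph()
  g <- graph_from_adj(A)
  memb <- two_star_membership()
  zi <- within_module_degree_z(g, memb)
  # hub of a star module: kappa = (4,1,1,1,1), mean 1.6, population sd 1.2
  expect_equal(unname(zi["a1"]), 2.0, tolerance = 1e-12)
  expect_equal(unname(zi["b1"]), 2.0, tolerance = 1e-12)
  # z-scores sum to zero inside each module
  expect_equal(sum(zi[paste0("a", 1:5)]), 0, tolerance = 1e-12)
  # clique module: all kappa equal, sd 0, all Zi = 0
  K <- matrix(1L, 4, 4) - diag(1L, 4)
  dimnames(K) <- list(letters[1:4], letters[1:4])
  ziK <- within_module_degree_z(graph_from_adj(K),
                                setNames(rep(1L, 4), letters[1:4]))
  expect_equal(unname(ziK), rep(0, 4))
  expect_error(within_module_degree_z(g, memb[-1]), "a1")
})

test_that("participation coefficient follows 1 - sum((k_it/k)^2)", {
  A <- two_star_graph()
  g <- graph_from_adj(A)
  memb <- two_star_membership()
  pv <- participation_coefficient(g, memb)
  # all links internal
  expect_equal(unname(pv["a1"]), 0)
  # k = 2 split evenly across two modules
  expect_equal(unname(pv["b2"]), 0.5, tolerance = 1e-12)

  # k = 4 split (2,1,1) across three modules: Pi = 1 - 6/16 = 0.625
  B <- matrix(0L, 7, 7)
  ids <- paste0("v", 1:7)
  dimnames(B) <- list(ids, ids)
  for (e in list(c(1, 2), c(1, 3), c(1, 4), c(1, 6), c(2, 3), c(4, 5), c(6, 7))) {
    B[e[1], e[2]] <- B[e[2], e[1]] <- 1L
  }
  membB <- setNames(c(1, 1, 1, 2, 2, 3, 3), ids)
  pvB <- participation_coefficient(graph_from_adj(B), membB)
  expect_equal(unname(pvB["v1"]), 0.625, tolerance = 1e-12)
})

test_that("Zi and Pi agree with brute-force oracles on random partitioned graphs", {
  set.seed(31)
  tested <- 0
  while (tested < 40) {
    n <- sample(5:10, 1)
    A <- rand_adjacency(n, p = runif(1, 0.4, 0.8))
    if (any(rowSums(A) == 0)) next
    tested <- tested + 1
    memb <- setNames(sample(1:3, n, replace = TRUE), rownames(A))
    g <- graph_from_adj(A)
    expect_equal(unname(within_module_degree_z(g, memb)), zi_oracle(A, memb),
                 tolerance = 1e-12)
    expect_equal(unname(participation_coefficient(g, memb)), pi_oracle(A, memb),
                 tolerance = 1e-12)
    pv <- participation_coefficient(g, memb)
    expect_true(all(pv >= -1e-12 & pv <= 1))
  }
})

test_that("role classification covers the four regions with exact boundaries", {
  expect_equal(as.character(classify_role(1.0, 0.70)), "connector")
  expect_equal(as.character(classify_role(3.0, 0.10)), "module_hub")
  expect_equal(as.character(classify_role(0, 0)), "peripheral")
  expect_equal(as.character(classify_role(2.6, 0.8)), "network_hub")
  # boundaries: Zi = 2.5 is a hub, Pi = 0.62 is not a connector
  expect_equal(as.character(classify_role(2.5, 0.62)), "module_hub")
  expect_equal(as.character(classify_role(2.5, 0.6200001)), "network_hub")
  expect_equal(as.character(classify_role(2.4999, 0.62)), "peripheral")
  # every point gets exactly one category
  set.seed(6)
  grid <- classify_role(runif(500, -2, 5), runif(500))
  expect_false(anyNA(grid))
})

test_that("node_role_table combines membership, Zi, Pi and category", {
  A <- two_star_graph()
  g <- graph_from_adj(A)
  tab <- node_role_table(g, partition = two_star_membership())
  expect_setequal(tab$node, rownames(A))
  expect_true(all(tab$category %in%
                    c("peripheral", "connector", "module_hub", "network_hub")))
  expect_equal(tab$Zi[tab$node == "a1"], 2.0, tolerance = 1e-12)
})
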