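# Synthetic-data generator.

test_that("generation is deterministic given the seed", {
  a <- generate_dataset(generator_config(seed = 5))
  b <- generate_dataset(generator_config(seed = 5))
  expect_identical(unclass(a$counts), unclass(b$counts))
  expect_identical(a$chemistry, b$chemistry)
  c2 <- generate_dataset(generator_config(seed = 6))
  expect_false(identical(unclass(a$counts), unclass(c2$counts)))
  # written files are byte-identical too
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_dataset(a, d1); write_dataset(b, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
})

test_that("the design and invariants of the generated tables hold", {
  d <- generate_dataset(generator_config(seed = 3))
  expect_equal(ncol(d$counts), 6 * 5)
  expect_equal(nrow(d$metadata), 30)
  expect_setequal(as.character(unique(d$metadata$treatment)), steppenet_treatments())
  expect_setequal(as.character(unique(d$metadata$layer)), steppenet_layers())
  # counts sum exactly to the drawn depths, all above the rarefaction target
  expect_true(all(colSums(d$counts) >= 4269))
  expect_true(all(d$counts >= 0))
  # taxonomy total over the table
  expect_true(all(rownames(d$counts) %in% names(d$taxonomy)))
  # chemistry aligned to community samples, replicate table at 6 plots
  expect_equal(d$chemistry$sample_id, colnames(d$counts))
  expect_equal(nrow(d$chemistry_reps), 6 * 5 * 6)
  # dominance structure: top-10 phyla carry > 95% of the community
  rel <- relative_abundance(aggregate_to_phylum(d$counts, d$taxonomy))
  top <- top_taxa_summary(rel, n_top = 10)
  expect_gt(mean(colSums(top[1:10, ])), 0.95)
  expect_gte(nrow(rel), 25)  # ~30 phyla observed
})

test_that("zero planted structure yields a near-empty network at St = 0.6", {
  cfg <- generator_config(modules = list(), water_beta = 0, nitrogen_beta = 0,
                          depth_beta = 0, seed = 11)
  d <- generate_dataset(cfg)
  sim <- suppressWarnings(spearman_matrix(prevalence_filter(d$counts)))
  net <- build_network(sim, st = 0.6)
  expect_lt(igraph::ecount(net) / choose(nrow(sim), 2), 0.005)
})

test_that("a planted module is recovered as a connected block", {
  cfg <- generator_config(seed = 7)
  d <- generate_dataset(cfg)
  sim <- suppressWarnings(spearman_matrix(prevalence_filter(d$counts)))
  net <- build_network(sim, st = 0.6)
  edges <- graph_edge_keys(net)
  modA <- sprintf("OTU_%03d", cfg$modules[[1]]$taxa)
  within <- combn(modA, 2, function(p) pair_keys(p[1], p[2]))
  expect_gt(mean(within %in% edges), 0.9)
  sub <- igraph::induced_subgraph(net, modA)
  expect_true(igraph::is_connected(sub))
})

test_that("chemistry effects point the planted directions", {
  d <- generate_dataset(generator_config(seed = 9))
  ch <- d$chemistry_reps
  m <- function(tr, v) mean(ch[[v]][ch$treatment == tr])
  expect_gt(m("WA", "moisture"), m("CK", "moisture"))
  expect_lt(m("WR", "moisture"), m("CK", "moisture"))
  expect_lt(m("NA", "pH"), m("CK", "pH"))
  expect_gt(m("NA", "NO3N"), m("CK", "NO3N"))
})

test_that("water addition raises Shannon diversity relative to control", {
  d <- generate_dataset(generator_config(seed = 7))
  dv <- diversity_table(rarefy(d$counts, seed = 2))
  tr <- d$metadata$treatment[match(dv$sample_id, d$metadata$sample_id)]
  means <- tapply(dv$shannon, tr, mean)
  expect_gt(means[["WA"]], means[["CK"]])
})

test_that("null pairs are reproducible and dimensioned as asked", {
  np1 <- generate_null_pair(n_samples = 10, n_taxa = 6, n_covars = 3, seed = 4)
  np2 <- generate_null_pair(n_samples = 10, n_taxa = 6, n_covars = 3, seed = 4)
  expect_identical(np1, np2)
  expect_equal(dim(np1$Y), c(10, 6))
  expect_equal(dim(np1$X), c(10, 3))
})

test_that("generator config validates module specs and YAML round-trips", {
  expect_error(generator_config(modules = list(
    list(taxa = 1:5, loading = 1), list(taxa = 4:8, loading = 1))), "disjoint")
  expect_error(generator_config(n_taxa = 10, modules = list(
    list(taxa = 8:12, loading = 1))), "range")
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("seed: 3", "replicates: 2"), path)
  cfg <- generator_config_from_yaml(path)
  expect_equal(cfg$seed, 3)
  expect_equal(cfg$replicates, 2)
  writeLines("bogus_field: 1", path)
  expect_error(generator_config_from_yaml(path), "bogus_field")
})
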