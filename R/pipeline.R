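# End-to-end orchestration: one call reproduces the full analysis on any
# conforming dataset and persists every intermediate table.

#' Configuration for a full pipeline run
#'
#' Collects the analysis parameters: rarefaction depth (default 4269 reads
#' per sample), similarity threshold St (default 0.6), node granularity
#' (phylum-aggregated by default, OTU-level optional), number of random
#' null replicates (default 100), RDA permutations (default 999),
#' significance level (default 0.05) and the master seed.
#'
#' @param dataset Either the list returned by [generate_dataset()] /
#'   assembled by hand (`counts`, `taxonomy`, `metadata`, `chemistry`,
#'   optional `chemistry_reps`) or a named list of file paths with the same
#'   elements.
#' @param depth Rarefaction depth.
#' @param st Similarity threshold in (0, 1).
#' @param node_level `"phylum"` or `"otu"`.
#' @param null_reps Random-network replicates per treatment.
#' @param n_perm RDA permutation count.
#' @param alpha Significance level for the chemistry ANOVA letters.
#' @param transform Species pre-transform for the RDA.
#' @param seed Master seed; all stage seeds derive from it.
#' @param out_dir Output directory.
#' @return List of class `"run_config"`.
#' @export
run_config <- function(dataset, out_dir, depth = 4269, st = 0.6,
                       node_level = c("phylum", "otu"), null_reps = 100,
                       n_perm = 999, alpha = 0.05,
                       transform = c("hellinger", "none", "log1p"),
                       seed = 1) {
  structure(list(dataset = dataset, out_dir = out_dir, depth = depth,
                 st = st, node_level = match.arg(node_level),
                 null_reps = null_reps, n_perm = n_perm, alpha = alpha,
                 transform = match.arg(transform), seed = seed),
            class = "run_config")
}

# Accept in-memory tables or paths.
.load_dataset <- function(dataset) {
  if (is.character(dataset$counts)) {
    list(
      counts = read_count_table(dataset$counts),
      taxonomy = read_taxonomy(dataset$taxonomy),
      metadata = read_sample_metadata(dataset$metadata),
      chemistry = read_chemistry(dataset$chemistry),
      chemistry_reps = if (!is.null(dataset$chemistry_reps)) {
        utils::read.delim(dataset$chemistry_reps, check.names = FALSE,
                          na.strings = "", stringsAsFactors = FALSE)
      }
    )
  } else {
    dataset
  }
}

#' Analyze one treatment's co-occurrence network
#'
#' The per-treatment arm of the pipeline: (optional) phylum aggregation,
#' strict-majority prevalence filter, Spearman similarity, thresholding at
#' St, topology report, Zi-Pi node roles, and a G(N, L) null summary at
#' the empirical node/link counts.  A warning is emitted when fewer than
#' 10 samples feed the correlation, where rank statistics get coarse.
#'
#' @param counts Rarefied [count_table()] restricted to one treatment's
#'   samples.
#' @param taxonomy Named taxon -> phylum vector.
#' @param st Similarity threshold.
#' @param node_level `"phylum"` or `"otu"`.
#' @param null_reps,seed Null-model replicates and seed.
#' @return List with `network`, `report`, `roles`, `null` (NULL when the
#'   network has no edges).
#' @export
analyze_treatment_network <- function(counts, taxonomy, st = 0.6,
                                      node_level = "phylum",
                                      null_reps = 100, seed = NULL) {
  if (ncol(counts) < 10L) {
    warning(sprintf("network built from only %d samples; rank correlations are coarse",
                    ncol(counts)), call. = FALSE)
  }
  tab <- if (node_level == "phylum") aggregate_to_phylum(counts, taxonomy) else counts
  tab <- prevalence_filter(tab)
  sim <- suppressWarnings(spearman_matrix(tab))
  node_tax <- if (node_level == "phylum") {
    stats::setNames(rownames(tab), rownames(tab))
  } else taxonomy[rownames(tab)]
  net <- build_network(sim, st = st, taxonomy = node_tax,
                       abundance = rowMeans(relative_abundance(tab)))
  if (igraph::ecount(net) == 0L) {
    return(list(network = net, report = NULL, roles = NULL, null = NULL))
  }
  part <- detect_modules(net)
  rep <- network_report(net, part)
  roles <- node_role_table(net, part)
  nul <- null_summary(igraph::vcount(net), igraph::ecount(net),
                      n_reps = null_reps, seed = seed)
  list(network = net, report = rep, roles = roles, null = nul)
}

# Table-2-shaped summary: one column per treatment, empirical block then
# random-null block.
.summary_table <- function(arms) {
  metric_rows <- c("Total nodes", "Total links", "Negative links (%)",
                   "Positive links (%)", "Avg. connectivity",
                   "Avg. path distance", "Avg. clustering coefficient",
                   "Modularity", "Random: Avg. path distance",
                   "Random: Avg. clustering coefficient", "Random: Modularity")
  cols <- lapply(arms, function(a) {
    if (is.null(a$report)) return(rep(NA_real_, length(metric_rows)))
    r <- a$report
    c(r$total_nodes, r$total_links, r$pct_negative_links,
      r$pct_positive_links, r$avg_connectivity, r$avg_path_distance,
      r$avg_clustering_coefficient, r$modularity,
      a$null$mean[["avg_path_distance"]],
      a$null$mean[["avg_clustering_coefficient"]],
      a$null$mean[["modularity"]])
  })
  out <- data.frame(metric = metric_rows, cols, check.names = FALSE)
  names(out)[-1L] <- names(arms)
  out
}

#' Run the full analysis pipeline
#'
#' Rarefies the count table, computes per-sample diversity, the top-10 +
#' others phylum composition, the per-layer chemistry ANOVA (when
#' replicate-level chemistry is available), the RDA of community
#' composition on soil chemistry with a Monte Carlo permutation test, and
#' one co-occurrence network per treatment (pooling that treatment's layer
#' samples) with topology report, node roles and random-network null.
#' All results are written as TSV (plus GraphML per network) into
#' `cfg$out_dir`; outputs are byte-identical across reruns with the same
#' configuration and seed.
#'
#' @param cfg A [run_config()].
#' @return Invisibly, a list with all in-memory results and `out_dir`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  data <- .load_dataset(cfg$dataset)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- c(sprintf("steppenet run, seed %s", format(cfg$seed)),
                 sprintf("depth %d, St %g, node level %s, null reps %d, permutations %d",
                         cfg$depth, cfg$st, cfg$node_level, cfg$null_reps, cfg$n_perm))

  counts <- count_table(unclass(data$counts))
  meta <- data$metadata
  if (!all(colnames(counts) %in% meta$sample_id)) {
    fail("stage metadata: sample(s) without metadata: %s",
         paste(setdiff(colnames(counts), meta$sample_id), collapse = ", "))
  }

  # 1. rarefaction
  rare <- withCallingHandlers(
    rarefy(counts, depth = cfg$depth, seed = derive_seed(cfg$seed, 1L)),
    warning = function(w) {
      log_lines <<- c(log_lines, paste("rarefy:", conditionMessage(w)))
      invokeRestart("muffleWarning")
    })
  meta <- meta[match(colnames(rare), meta$sample_id), , drop = FALSE]
  log_lines <- c(log_lines, sprintf("rarefied to %d reads, %d samples retained",
                                    cfg$depth, ncol(rare)))

  # 2. diversity
  div <- diversity_table(rare)
  write_tsv(div, file.path(cfg$out_dir, "diversity.tsv"))

  # 3. composition: phylum aggregation, top-10 + others
  phyl <- aggregate_to_phylum(rare, data$taxonomy)
  rel <- relative_abundance(phyl)
  top10 <- top_taxa_summary(rel, n_top = 10)
  write_tsv(data.frame(phylum = rownames(top10), top10, check.names = FALSE),
            file.path(cfg$out_dir, "relative_abundance_top10.tsv"))

  # 4. chemistry ANOVA (replicate level)
  chem_anova <- NULL
  if (!is.null(data$chemistry_reps)) {
    chem_anova <- chemistry_anova_table(data$chemistry_reps, alpha = cfg$alpha)
    write_tsv(chem_anova, file.path(cfg$out_dir, "chemistry_anova.tsv"))
  }

  # 5. RDA + permutation test on community ~ chemistry
  chem <- data$chemistry
  chem <- chem[match(colnames(rare), chem$sample_id), , drop = FALSE]
  if (anyNA(chem$sample_id)) fail("stage rda: chemistry missing for some samples")
  X <- as.matrix(chem[chemistry_variables()])
  Y <- t(unclass(rel))
  rda <- rda_fit(Y, X, transform = cfg$transform)
  mc <- monte_carlo_test(Y, X, n_perm = cfg$n_perm,
                         seed = derive_seed(cfg$seed, 2L),
                         transform = cfg$transform)
  rda_sum <- data.frame(
    axis = seq_along(rda$eig),
    eigenvalue = unname(rda$eig),
    pct_total_variance = unname(rda$pct_total),
    pct_constrained_variance = unname(rda$pct_constrained)
  )
  write_tsv(rda_sum, file.path(cfg$out_dir, "rda_axes.tsv"))
  write_tsv(data.frame(sample_id = rownames(rda$site_scores), rda$site_scores),
            file.path(cfg$out_dir, "rda_site_scores.tsv"))
  write_tsv(data.frame(taxon = rownames(rda$species_scores), rda$species_scores),
            file.path(cfg$out_dir, "rda_species_scores.tsv"))
  write_tsv(data.frame(covariate = rownames(rda$biplot_scores), rda$biplot_scores),
            file.path(cfg$out_dir, "rda_biplot_scores.tsv"))
  write_tsv(data.frame(statistic = mc$statistic, n_perm = mc$n_perm,
                       p_value = mc$p_value),
            file.path(cfg$out_dir, "rda_permutation_test.tsv"))
  log_lines <- c(log_lines,
                 sprintf("RDA axis1 %.4f%%, axis2 %.4f%% of total variance; permutation p = %.4g",
                         rda$pct_total[1], ifelse(length(rda$pct_total) > 1, rda$pct_total[2], NA),
                         mc$p_value))

  # 6. per-treatment networks
  treatments <- levels(meta$treatment)[levels(meta$treatment) %in% meta$treatment]
  arms <- list()
  for (k in seq_along(treatments)) {
    tr <- treatments[k]
    sub <- rare[, colnames(rare) %in% meta$sample_id[meta$treatment == tr], drop = FALSE]
    arm <- withCallingHandlers(
      analyze_treatment_network(count_table(unclass(sub)), data$taxonomy,
                                st = cfg$st, node_level = cfg$node_level,
                                null_reps = cfg$null_reps,
                                seed = derive_seed(cfg$seed, 10L + k)),
      warning = function(w) {
        log_lines <<- c(log_lines, sprintf("network %s: %s", tr, conditionMessage(w)))
        invokeRestart("muffleWarning")
      })
    arms[[tr]] <- arm
    if (!is.null(arm$report)) {
      write_edge_list(arm$network, file.path(cfg$out_dir, sprintf("network_%s_edges.tsv", tr)))
      write_graphml(arm$network, file.path(cfg$out_dir, sprintf("network_%s.graphml", tr)))
      write_tsv(arm$roles, file.path(cfg$out_dir, sprintf("node_roles_%s.tsv", tr)))
      log_lines <- c(log_lines,
                     sprintf("network %s: %d nodes, %d links, Q = %.4f (null mean %.4f)",
                             tr, arm$report$total_nodes, arm$report$total_links,
                             arm$report$modularity, arm$null$mean[["modularity"]]))
    } else {
      log_lines <- c(log_lines, sprintf("network %s: no edges above St = %g", tr, cfg$st))
    }
  }
  summary_tab <- .summary_table(arms)
  write_tsv(summary_tab, file.path(cfg$out_dir, "network_summary.tsv"))

  # provenance: serialized config + run log (no timestamps, reruns are
  # byte-identical)
  cfg_out <- cfg[setdiff(names(cfg), c("dataset", "out_dir"))]
  yaml::write_yaml(cfg_out, file.path(cfg$out_dir, "run_config.yaml"))
  writeLines(log_lines, file.path(cfg$out_dir, "run_log.txt"))

  invisible(list(out_dir = cfg$out_dir, diversity = div, top10 = top10,
                 chemistry_anova = chem_anova, rda = rda,
                 permutation = mc, networks = arms, summary = summary_tab))
}

#' Build a run configuration from a YAML file
#'
#' The YAML must carry a `dataset` block of file paths (`counts`,
#' `taxonomy`, `metadata`, `chemistry`, optional `chemistry_reps`) and an
#' `out_dir`; other [run_config()] fields are optional.
#'
#' @param path Path to a YAML file.
#' @return A [run_config()].
#' @export
run_config_from_yaml <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) fail("unknown run config field(s): %s",
                            paste(unknown, collapse = ", "))
  do.call(run_config, vals)
}
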