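# Synthetic OTU-table generator with planted co-occurrence structure and
# treatment-linked soil chemistry, so the whole pipeline can be exercised
# and validated without sequencing data.

# 30 bacterial phylum names; the first ten are the dominant ones.
.phylum_pool <- function() c(
  "Actinobacteria", "Proteobacteria", "Chloroflexi", "Acidobacteria",
  "Cyanobacteria", "Bacteroidetes", "Planctomycetes", "Verrucomicrobia",
  "Gemmatimonadetes", "Firmicutes",
  "Chlorobi", "Nitrospirae", "Armatimonadetes", "Elusimicrobia",
  "Fibrobacteres", "Spirochaetes", "Tenericutes", "Deinococcus-Thermus",
  "Chlamydiae", "Fusobacteria", "Aquificae", "Thermotogae",
  "Caldiserica", "Dictyoglomi", "Synergistetes", "Lentisphaerae",
  "Deferribacteres", "Thermodesulfobacteria", "Calditrichaeota",
  "unassigned")

# Per-layer chemistry baselines for the control, in the order of
# steppenet_layers(): pH, moisture %, TC %, TN %, NO3-N and NH4-N mg/kg.
.chem_baselines <- function() list(
  pH       = c(8.03, 8.25, 8.52, 8.72, 8.63),
  moisture = c(1.17, 3.74, 5.84, 5.72, 5.36),
  TC       = c(1.63, 1.72, 1.73, 1.52, 1.61),
  TN       = c(0.178, 0.183, 0.185, 0.163, 0.143),
  NO3N     = c(4.70, 4.86, 3.43, 3.52, 3.04),
  NH4N     = c(2.35, 1.75, 1.71, 1.89, 2.04)
)

#' Configuration for the synthetic-data generator
#'
#' Defines the study conditions the generator emulates: a 6-treatment x
#' 5-layer design, ~150 OTUs over 30 phyla with a top-10 dominance
#' structure, sequencing depths comfortably above the 4269-read
#' rarefaction target, two planted correlation modules whose latent-factor
#' loading puts the within-module correlation near 0.9, water- and
#' nitrogen-responsive taxon sets, and chemistry effects matching the
#' direction and rough size of the significant treatment contrasts
#' (moisture up under water addition, pH down and NO3-N up under nitrogen
#' addition).
#'
#' @param n_taxa Number of OTUs (default 150).
#' @param treatments,layers Design levels (defaults: the six treatments and
#'   five depth bins).
#' @param replicates Sequenced replicates per treatment x layer (default 1,
#'   i.e. replicate plots pooled into one sample).
#' @param chem_replicates Chemistry replicate plots per treatment x layer
#'   (default 6), used for the per-layer ANOVA.
#' @param depth_min,depth_mean,depth_dispersion Sequencing depths are
#'   drawn as `depth_min` plus a negative-binomial overage with mean
#'   `depth_mean - depth_min` and the given dispersion, so every sample
#'   clears the floor (default 10000 reads, the usual acceptance bar for a
#'   sequenced sample, and comfortably above the 4269-read rarefaction
#'   target).
#' @param modules List of planted modules, each
#'   `list(taxa = <indices>, loading = <w>)`; taxon sets must be disjoint.
#'   With loading w and noise sd s the within-module latent correlation is
#'   `w^2 / (w^2 + s^2)` (0.9 at the defaults).  The default modules sit at
#'   subdominant abundance ranks (about 2% of community mass each) so their
#'   latent swings do not compositionally couple the rest of the community.
#' @param water_taxa,water_beta Taxa responding to the water axis (+1 for
#'   WA/NAWA, -1 for WR/NAWR) and their log-abundance coefficient.
#' @param nitrogen_taxa,nitrogen_beta Taxa responding to nitrogen addition
#'   (indicator for NA/NAWA/NAWR) and their coefficient.
#' @param depth_taxa,depth_beta Surface-associated taxa whose abundance
#'   declines down the profile (coefficient on the standardized layer
#'   index).  The default takes the members of one dominant phylum
#'   (Cyanobacteria under the default taxonomy assignment) that lie
#'   outside the planted modules, emulating the
#'   concentration of phototrophs in the top layers, and gives the
#'   phylum-level composition a depth gradient the constrained ordination
#'   can resolve.
#' @param noise_sd Per-taxon log-abundance noise sd (default 0.5).
#' @param chem_effects List of chemistry effect sizes: `moisture_wa`,
#'   `moisture_wr`, `ph_na`, `no3_na`, `nh4_na`, `tn_na`.
#' @param chem_noise_sd Named vector of per-variable replicate noise sds.
#' @param seed Master seed; a fixed seed makes [generate_dataset()] output
#'   byte-identical.
#' @return List of class `"generator_config"`.
#' @export
generator_config <- function(n_taxa = 150,
                             treatments = steppenet_treatments(),
                             layers = steppenet_layers(),
                             replicates = 1,
                             chem_replicates = 6,
                             depth_min = 10000,
                             depth_mean = 12000,
                             depth_dispersion = 30,
                             modules = list(
                               list(taxa = 31:38, loading = 1.5),
                               list(taxa = 41:48, loading = 1.5)
                             ),
                             water_taxa = 11:30,
                             water_beta = 0.8,
                             nitrogen_taxa = 51:70,
                             nitrogen_beta = -0.8,
                             depth_taxa = setdiff(seq(5, 115, by = 10), 31:48),
                             depth_beta = -0.9,
                             noise_sd = 0.5,
                             chem_effects = list(
                               moisture_wa = 1.2, moisture_wr = -0.6,
                               ph_na = -0.6, no3_na = 2.0,
                               nh4_na = 0.4, tn_na = 0.005
                             ),
                             chem_noise_sd = c(pH = 0.15, moisture = 0.35,
                                               TC = 0.08, TN = 0.01,
                                               NO3N = 0.30, NH4N = 0.20),
                             seed = 1) {
  cfg <- list(n_taxa = n_taxa, treatments = treatments, layers = layers,
              replicates = replicates, chem_replicates = chem_replicates,
              depth_min = depth_min, depth_mean = depth_mean,
              depth_dispersion = depth_dispersion,
              modules = modules, water_taxa = water_taxa,
              water_beta = water_beta, nitrogen_taxa = nitrogen_taxa,
              nitrogen_beta = nitrogen_beta, depth_taxa = depth_taxa,
              depth_beta = depth_beta, noise_sd = noise_sd,
              chem_effects = chem_effects, chem_noise_sd = chem_noise_sd,
              seed = seed)
  all_mod <- unlist(lapply(modules, `[[`, "taxa"))
  if (anyDuplicated(all_mod)) fail("module taxon sets must be disjoint")
  if (length(all_mod) && (max(all_mod) > n_taxa || min(all_mod) < 1)) {
    fail("module taxon indices out of range")
  }
  for (set in list(water_taxa, nitrogen_taxa, depth_taxa)) {
    if (length(set) && (max(set) > n_taxa || min(set) < 1)) {
      fail("effect taxon indices out of range for n_taxa = %d", n_taxa)
    }
  }
  structure(cfg, class = "generator_config")
}

# Baseline log-abundance profile: steep decay over the dominant taxa, then
# a long shallow tail so rare taxa stay observable at realistic depths.
.baseline_logabund <- function(n_taxa) {
  i <- seq_len(n_taxa)
  ifelse(i <= 50, -0.10 * i, -5 - 0.015 * (i - 50))
}

# Taxon -> phylum assignment: the first 120 taxa cycle through the ten
# dominant phyla (so they pool > 95% of the mass), the rest spread over
# the 20 rare phyla.
.assign_phyla <- function(n_taxa) {
  pool <- .phylum_pool()
  n_major <- min(n_taxa, ceiling(0.8 * n_taxa))
  out <- character(n_taxa)
  out[seq_len(n_major)] <- pool[((seq_len(n_major) - 1L) %% 10L) + 1L]
  if (n_taxa > n_major) {
    rest <- seq.int(n_major + 1L, n_taxa)
    out[rest] <- pool[((rest - n_major - 1L) %% 20L) + 11L]
  }
  out
}

#' Generate a synthetic dataset with planted structure
#'
#' Per sample j, the latent log-abundance of taxon i is
#' `lambda_ij = b_i + sum_m w_im f_mj + beta_i . x_j + eps_ij`, with
#' `f_mj ~ N(0, 1)` a module factor shared by all module members within a
#' sample (planting co-occurrence), `x_j` the treatment design vector
#' (water axis and nitrogen indicator) and `eps_ij ~ N(0, noise_sd)`.
#' Counts are multinomial draws of the sample's sequencing depth from
#' `softmax(lambda_.j)`, so each column sums exactly to its drawn depth.
#' Chemistry is drawn per replicate plot around layer baselines with
#' treatment effects (water addition raises moisture, nitrogen addition
#' lowers pH and raises NO3-N); the per-sample chemistry table holds the
#' replicate means, aligned to the community samples.
#'
#' @param cfg A [generator_config()].
#' @return List with `counts` ([count_table()]), `taxonomy` (named
#'   vector), `metadata` (data.frame), `chemistry` (per community sample),
#'   `chemistry_reps` (per replicate plot), and `config`.
#' @export
generate_dataset <- function(cfg = generator_config()) {
  stopifnot(inherits(cfg, "generator_config"))
  design <- expand.grid(replicate = seq_len(cfg$replicates),
                        layer = cfg$layers, treatment = cfg$treatments,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  design <- design[, c("treatment", "layer", "replicate")]
  n_s <- nrow(design)
  sample_ids <- sprintf("%s_L%d_r%d", design$treatment,
                        match(design$layer, cfg$layers), design$replicate)
  taxon_ids <- sprintf("OTU_%03d", seq_len(cfg$n_taxa))
  b <- .baseline_logabund(cfg$n_taxa)
  x_water <- ifelse(design$treatment %in% c("WA", "NAWA"), 1,
                    ifelse(design$treatment %in% c("WR", "NAWR"), -1, 0))
  x_nitro <- as.numeric(design$treatment %in% c("NA", "NAWA", "NAWR"))
  x_depth <- as.numeric(scale(match(design$layer, cfg$layers)))
  beta <- matrix(0, cfg$n_taxa, 3L)
  beta[cfg$water_taxa, 1L] <- cfg$water_beta
  beta[cfg$nitrogen_taxa, 2L] <- cfg$nitrogen_beta
  beta[cfg$depth_taxa, 3L] <- cfg$depth_beta

  if (cfg$depth_mean <= cfg$depth_min) fail("depth_mean must exceed depth_min")
  out <- with_seed(cfg$seed, {
    depth <- cfg$depth_min + stats::rnbinom(n_s, mu = cfg$depth_mean - cfg$depth_min,
                                            size = cfg$depth_dispersion)
    f <- matrix(stats::rnorm(length(cfg$modules) * n_s), length(cfg$modules), n_s)
    eps <- matrix(stats::rnorm(cfg$n_taxa * n_s, sd = cfg$noise_sd), cfg$n_taxa, n_s)
    lambda <- matrix(b, cfg$n_taxa, n_s) + eps +
      beta %*% rbind(x_water, x_nitro, x_depth)
    for (m in seq_along(cfg$modules)) {
      mod <- cfg$modules[[m]]
      lambda[mod$taxa, ] <- lambda[mod$taxa, ] +
        matrix(mod$loading * f[m, ], length(mod$taxa), n_s, byrow = TRUE)
    }
    counts <- matrix(0L, cfg$n_taxa, n_s)
    for (j in seq_len(n_s)) {
      p <- exp(lambda[, j] - max(lambda[, j]))
      counts[, j] <- stats::rmultinom(1L, depth[j], p / sum(p))
    }
    dimnames(counts) <- list(taxon_ids, sample_ids)

    # chemistry: replicate plots per treatment x layer
    base <- .chem_baselines()
    eff <- cfg$chem_effects
    chem_design <- expand.grid(replicate = seq_len(cfg$chem_replicates),
                               layer = cfg$layers, treatment = cfg$treatments,
                               KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    li <- match(chem_design$layer, cfg$layers)
    w_plus <- chem_design$treatment %in% c("WA", "NAWA")
    w_minus <- chem_design$treatment %in% c("WR", "NAWR")
    n_plus <- chem_design$treatment %in% c("NA", "NAWA", "NAWR")
    nr <- nrow(chem_design)
    sdv <- cfg$chem_noise_sd
    chem <- data.frame(
      sample_id = sprintf("%s_L%d_p%d", chem_design$treatment, li,
                          chem_design$replicate),
      treatment = chem_design$treatment,
      layer = chem_design$layer,
      replicate = chem_design$replicate,
      pH = base$pH[li] + eff$ph_na * n_plus + stats::rnorm(nr, sd = sdv[["pH"]]),
      moisture = pmax(0.05, base$moisture[li] + eff$moisture_wa * w_plus +
                        eff$moisture_wr * w_minus + stats::rnorm(nr, sd = sdv[["moisture"]])),
      TC = pmax(0.05, base$TC[li] + stats::rnorm(nr, sd = sdv[["TC"]])),
      TN = pmax(0.01, base$TN[li] + eff$tn_na * n_plus + stats::rnorm(nr, sd = sdv[["TN"]])),
      NO3N = pmax(0.05, base$NO3N[li] + eff$no3_na * n_plus + stats::rnorm(nr, sd = sdv[["NO3N"]])),
      NH4N = pmax(0.05, base$NH4N[li] + eff$nh4_na * n_plus + stats::rnorm(nr, sd = sdv[["NH4N"]])),
      stringsAsFactors = FALSE
    )
    list(counts = counts, chem = chem)
  })

  metadata <- data.frame(sample_id = sample_ids, design, stringsAsFactors = FALSE)
  # per-community-sample chemistry: replicate means by treatment x layer
  agg <- stats::aggregate(out$chem[chemistry_variables()],
                          by = list(treatment = out$chem$treatment,
                                    layer = out$chem$layer), FUN = mean)
  key <- paste(metadata$treatment, metadata$layer)
  idx <- match(key, paste(agg$treatment, agg$layer))
  chemistry <- data.frame(sample_id = sample_ids,
                          agg[idx, chemistry_variables(), drop = FALSE],
                          row.names = NULL, stringsAsFactors = FALSE)
  list(
    counts = count_table(out$counts),
    taxonomy = stats::setNames(.assign_phyla(cfg$n_taxa), taxon_ids),
    metadata = validate_sample_metadata(metadata, treatments = cfg$treatments,
                                        layers = cfg$layers),
    chemistry = validate_chemistry(chemistry),
    chemistry_reps = out$chem,
    config = cfg
  )
}

#' Generate an independent (Y, X) pair for null calibration
#'
#' Draws a community matrix and a covariate matrix from two separate
#' random streams, with no shared structure, so any association between
#' them is pure chance.  Used to check that the permutation test's
#' p-values are approximately uniform under the null.
#'
#' @param n_samples,n_taxa,n_covars Dimensions (defaults 30, 40, 4).
#' @param depth Sequencing depth per sample (default 5000).
#' @param seed Integer seed.
#' @return List with `Y` (samples x taxa counts) and `X` (samples x
#'   covariates).
#' @export
generate_null_pair <- function(n_samples = 30, n_taxa = 40, n_covars = 4,
                               depth = 5000, seed = NULL) {
  b <- .baseline_logabund(n_taxa)
  Y <- with_seed(seed, {
    lam <- matrix(b, n_taxa, n_samples) +
      matrix(stats::rnorm(n_taxa * n_samples, sd = 0.5), n_taxa, n_samples)
    vapply(seq_len(n_samples), function(j) {
      p <- exp(lam[, j] - max(lam[, j]))
      stats::rmultinom(1L, depth, p / sum(p))[, 1L]
    }, integer(n_taxa))
  })
  X <- with_seed(derive_seed(seed, 991L),
                 matrix(stats::rnorm(n_samples * n_covars), n_samples, n_covars,
                        dimnames = list(NULL, paste0("x", seq_len(n_covars)))))
  list(Y = t(Y), X = X)
}

#' Write a generated dataset to a directory of TSV files
#'
#' Emits `counts.tsv`, `taxonomy.tsv`, `metadata.tsv`, `chemistry.tsv`
#' and `chemistry_reps.tsv` in the package's input formats.
#'
#' @param dataset Result of [generate_dataset()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_count_table(dataset$counts, file.path(dir, "counts.tsv"))
  write_taxonomy(dataset$taxonomy, file.path(dir, "taxonomy.tsv"))
  write_tsv(dataset$metadata, file.path(dir, "metadata.tsv"))
  write_tsv(dataset$chemistry, file.path(dir, "chemistry.tsv"))
  write_tsv(dataset$chemistry_reps, file.path(dir, "chemistry_reps.tsv"))
  invisible(dir)
}

#' Build a generator configuration from a YAML file
#'
#' Any field of [generator_config()] may be set; missing fields keep their
#' defaults.  Quote the nitrogen-addition treatment label (`"NA"`) in the
#' YAML so it stays a string.
#'
#' @param path Path to a YAML file.
#' @return A [generator_config()].
#' @export
generator_config_from_yaml <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(generator_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) fail("unknown generator config field(s): %s",
                            paste(unknown, collapse = ", "))
  do.call(generator_config, vals)
}
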