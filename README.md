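# steppenet

Co-occurrence network analysis and community statistics for soil
microbiome surveys.

`steppenet` implements the standard desk analysis applied to an OTU count
table from a multi-treatment soil experiment (e.g. a 6-treatment x
5-depth-layer water/nitrogen manipulation in a steppe grassland):

* **Preprocessing** — rarefaction to a common depth (default 4269 reads per
  sample, without replacement), strict-majority prevalence filtering
  (a taxon is kept iff present in more than half of all samples), and
  phylum-level aggregation.
* **Co-occurrence networks** — pairwise Spearman rank correlation between
  taxon abundance profiles; an undirected signed edge wherever
  |rho| > St (similarity threshold, default St = 0.6); topology metrics
  (total nodes/links, positive/negative link percentages, average
  connectivity 2L/N, average path distance, average clustering
  coefficient, greedy modularity Q).
* **Node roles** — within-module degree z-score Zi and among-module
  participation coefficient Pi, with the four-region classification
  (peripheral / connector / module hub / network hub at thresholds
  Zi = 2.5 and Pi = 0.62); connectors and hubs are the usual keystone
  candidates.
* **Random nulls** — Erdős–Rényi G(N, L) networks at the empirical node
  and link counts; mean path distance, clustering and modularity over
  replicates for the empirical-vs-random contrast.
* **Community statistics** — Shannon–Wiener diversity (nats), richness,
  relative-abundance change summaries (top-10 phyla + "others"), one-way
  ANOVA of soil chemistry per layer with Tukey-HSD compact letter display.
* **Constrained ordination** — redundancy analysis (RDA) of
  (Hellinger-transformed) community composition on soil-chemistry
  covariates, with a seeded Monte Carlo permutation test on the
  constrained variance (add-one p-value).
* **Synthetic data** — a seeded generator (latent-factor log-normal →
  multinomial counts) with planted correlation modules,
  treatment-responsive taxon sets and treatment-linked chemistry, so every
  stage can be exercised and validated without sequencing data.

The model at the network core: for taxa i, j with abundance profiles
across samples, rho_ij is the Pearson correlation of mid-ranks; edges
satisfy |rho_ij| > St and keep sign(rho_ij). Modularity of a partition is
Q = Σ_m [ l_m/L − (d_m/2L)² ]; node roles use
Zi = (κ_i − mean_m κ)/sd_m κ and Pi = 1 − Σ_t (k_it/k_i)².

## Worked example

```r
library(steppenet)

dataset <- generate_dataset(generator_config(seed = 1))
res <- run_pipeline(run_config(dataset, out_dir = "analysis", seed = 2))

res$networks[["CK"]]$report
#> co-occurrence network report
#>   nodes 21, links 55 (47.27% +, 52.73% -)
#>   avg connectivity 5.2381, path distance 2.0381, clustering 0.4908
#>   modularity 0.3212 (3 modules)

res$networks[["CK"]]$null
#> G(N = 21, L = 55) null, 100 replicates
#>   avg_path_distance: 1.9244 (sd 0.0306)
#>   avg_clustering_coefficient: 0.2598 (sd 0.0535)
#>   modularity: 0.2499 (sd 0.0262)

res$rda
#> RDA (hellinger transform): constrained 0.02209 of total 0.04338 (50.91%)
#>   axis 1: 42.25% of total (82.99% of constrained)
#>   axis 2: 4.47% of total (8.78% of constrained)
#>   ...

res$permutation
#> Monte Carlo permutation test: trace = 0.02209, p = 0.001 (999 permutations)
```

The control network retains 21 phylum-level nodes and 55 supra-threshold
links; its modularity (0.32) clearly exceeds the mean modularity of
size-matched random networks (0.25), the usual signature of a
compartmentalized community. The RDA finds that soil chemistry constrains
about half of the community variance, dominated by axis 1, and the
permutation test puts that association at the smallest attainable p
(1/1000). The output directory holds every table as TSV (diversity,
top-10 composition, chemistry ANOVA with letters, RDA scores, per-network
edge lists + GraphML, node roles, and a one-page summary with one column
per treatment and an empirical + random block).

A thin CLI wraps the same functions:

```sh
exec/steppenet simulate --out data_dir --seed 1
exec/steppenet run --config run.yaml
exec/steppenet network --counts data_dir/counts.tsv --out net_dir --st 0.6
exec/steppenet null --nodes 27 --links 306 --reps 100 --seed 1
```

## Vignette

`vignettes/steppenet-methods.Rmd` describes the statistical model, every
tunable parameter with its default and rationale, what the synthetic
generator does and does not emulate, and the package's numerical choices
and limitations.
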