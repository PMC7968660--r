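---
title: "Methods: co-occurrence networks and community statistics in steppenet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: co-occurrence networks and community statistics in steppenet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`steppenet` packages the desk half of a soil-microbiome survey: everything
downstream of the OTU table. This vignette explains the statistical
procedures, the parameters that matter, what the synthetic-data generator
does and does not emulate, and the numerical decisions baked into the
implementation.

## The pipeline

Starting from a taxon-by-sample count table, per-sample metadata
(treatment, depth layer, replicate), a taxon-to-phylum map, and a
soil-chemistry table, `run_pipeline()` performs:

1. **Rarefaction** to a common depth (default 4269 reads/sample).
   Subsampling is without replacement (multivariate hypergeometric), so a
   sample below the target depth cannot be normalized and is dropped with
   a warning rather than padded. Rarefaction equalizes sequencing effort
   before any diversity or correlation statistic; it is seeded and
   reproducible.
2. **Diversity**: Shannon–Wiener index H = −Σ p log p per sample (nats by
   default; the log base is a parameter because conventions differ), and
   richness (taxa with positive count).
3. **Composition**: phylum aggregation (exact count conservation per
   sample), relative abundances, and the top-10-plus-"others"
   presentation. Relative-abundance *changes* between a treatment and the
   control are reported as relative percent change,
   100·(p_t − p_ck)/p_ck, not percentage-point differences — the two are
   easy to conflate, and the relative form is the one that makes "+11%"
   statements comparable across phyla of very different abundance.
4. **Chemistry ANOVA**: classical one-way ANOVA per layer and variable
   across treatments on replicate plots, with Tukey HSD pairwise
   comparisons at α = 0.05 condensed into a compact letter display
   (insert-and-absorb), so that two treatments share a letter exactly
   when their adjusted p ≥ α.
5. **Co-occurrence networks**, one per treatment, pooling that
   treatment's layer samples (replicates, when present, enter as
   additional samples).
6. **RDA** of community composition on the six chemistry covariates with
   a Monte Carlo permutation test.

All outputs are plain TSV (plus GraphML per network); a rerun with the
same configuration and seed is byte-identical. Every summary number can
be recomputed from the persisted intermediates — there is no hidden
state.

## Network construction and topology

The similarity matrix is Spearman's rho between taxon abundance profiles:
the Pearson correlation of mid-ranks, with tied values receiving average
ranks. Rank correlation is used because count data are non-normal,
zero-inflated and compositional; any strictly monotone distortion of a
taxon's abundances leaves the matrix unchanged. Taxa that are constant
across the pooled samples have no defined rank correlation and are
assigned rho = 0 against all partners (with a warning), which simply
excludes them from the network.

An edge joins taxa i and j iff |rho_ij| > St, *strictly*; the edge keeps
the correlation value and its sign. The default threshold St = 0.6 is the
conventional cutoff for these networks and is an explicit parameter —
this package deliberately does not implement random-matrix-theory
threshold scanning, which needs far denser data than a pooled treatment
provides. Before any metric is computed, nodes without a surviving edge
are removed; node counts therefore vary between treatments sharing a
taxon pool. Two conventions follow from the data rather than the math and
are documented here as choices:

* all topology metrics and community detection run on the **unsigned**
  skeleton; the sign is reported per edge (negative-link percentages are
  part of the report) but does not enter path lengths or modularity;
* **average path distance** is the mean shortest-path length over node
  pairs within the same connected component; disconnected pairs are
  excluded (and counted in a message) rather than given an arbitrary
  finite distance.

Average connectivity is 2L/N (the mean degree). Average clustering is the
mean of local coefficients C_i = 2e_i/(k_i(k_i−1)) with C_i = 0 for
degree < 2. Modularity Q = Σ_m [l_m/L − (d_m/2L)²] is maximized by
greedy agglomerative (fast-greedy) merging; the merge tree is cut at the
step of maximal Q by the package itself because the library's own cut can
land one merge early when the optimum is a floating-point-noise zero
(e.g. a single clique, whose correct answer is one module with Q = 0).
The greedy optimizer is parameter-free and deterministic for a given
graph, which matters more here than squeezing out the last few percent of
Q; tests verify it never exceeds the exhaustive optimum on small graphs
and attains it on planted two-block graphs.

## Node roles and the random null

Within a module partition, each node gets a within-module degree z-score
Zi = (κ_i − mean κ)/sd κ, where κ counts links into the node's own module
and mean/sd run over that module's members. The sd is the population sd
(divide by module size): the module *is* the population, not a sample
from one; a module whose members all have equal κ has sd 0 and Zi := 0.
The participation coefficient Pi = 1 − Σ_t (k_it/k_i)² measures how
evenly a node's links spread over modules (0 = fully internal).

Roles partition the (Zi, Pi) plane at Zi = 2.5 and Pi = 0.62: peripheral
(low/low), connector (low Zi, Pi > 0.62), module hub (Zi ≥ 2.5,
Pi ≤ 0.62), network hub (high/high). Published descriptions of this
scheme are not always consistent about boundary inclusion or the
hub/connector labels; the package fixes one convention — Zi = 2.5 is a
hub, Pi = 0.62 is not a connector — and applies it everywhere, so every
point including boundaries lands in exactly one category.

The null model is G(N, L): exactly L distinct unordered pairs drawn
uniformly among N nodes, matching the empirical node and link counts
while erasing all structure — the "every link equally probable" null.
Degree-preserving rewiring is deliberately not the default; the uniform
model is the one matching the reported comparisons this pipeline mirrors.
`null_summary()` repeats the draw (default 100 replicates, seeded) and
summarizes the same three metrics used empirically. In the dense regime
typical of these networks (e.g. N = 27, L = 306, density 0.87) the null's
clustering concentrates at the density and its modularity is small, so a
structured empirical network shows Q above the null mean — the contrast
the tests assert on synthetic data.

## Redundancy analysis

RDA projects the column-centered community matrix onto the column space
of the standardized covariates and eigendecomposes the fitted values. Two
percentages are reported per axis — of *total* community variance and of
*constrained* variance — because published axis percentages are often
ambiguous between the two; both are available and labelled.

The species matrix is Hellinger-transformed by default (square root of
relative abundances). Count composition is not Euclidean; the Hellinger
transform is the standard way to make RDA's linear geometry defensible
for abundance data. `"none"` and `"log1p"` are provided because the right
choice depends on the data and no transform can be inferred from a
published percentage after the fact.

The "Monte Carlo" significance test permutes whole rows of the covariate
matrix (optionally within strata, e.g. layers, though unrestricted
permutation is the default), recomputes the constrained trace each time,
and reports p = (1 + #{perm ≥ obs})/(1 + n_perm). The add-one rule keeps
p strictly positive; with the default 999 permutations the smallest
attainable p is 1/1000. The same projection code computes the observed
and permuted statistics, and a test cross-checks it against the
ordination engine's constrained inertia. Collinear covariates are
rejected by name rather than silently dropped.

## The synthetic-data generator

`generate_dataset()` emulates the *post-clustering* state of a
6-treatment × 5-layer soil survey; it generates no reads and no
sequences. Per sample j, taxon i has latent log-abundance

λ_ij = b_i + Σ_m w_im f_mj + β_i·x_j + ε_ij

with b a fixed decay profile (steep over the ~50 dominant taxa, long
shallow tail), f_mj ~ N(0,1) module factors shared within a sample, x_j
the design vector (water axis ±1, nitrogen indicator, standardized depth
index) and ε_ij ~ N(0, 0.5). Counts are multinomial at the sample's
sequencing depth from softmax(λ), so columns sum exactly to their drawn
depth; depths are a floor of 10 000 reads plus a negative-binomial
overage (mean 12 000), reflecting that a sequenced sample below ~10k
reads would have been excluded upstream.

Key default choices, made once:

* **Planted modules**: two disjoint 8-taxon blocks at subdominant ranks
  (~2% of community mass each) with loading w = 1.5, giving within-module
  latent correlation w²/(w²+σ²) = 0.9. Placing modules among dominant
  taxa instead would make their swings compositionally couple the whole
  community (softmax renormalization) and manufacture spurious
  between-module correlations — an instructive failure mode, but not the
  intended test bed.
* **Treatment effects**: a 20-taxon subdominant set responds positively
  to the water axis (raising evenness, hence Shannon, under water
  addition), a 20-taxon set responds negatively to nitrogen addition, and
  the members of one dominant phylum (Cyanobacteria in the default
  taxonomy) decline with depth, giving the phylum table a gradient the
  RDA can resolve against the depth-varying chemistry.
* **Chemistry**: per-layer control baselines with treatment shifts
  (moisture +1.2 % under water addition, −0.6 % under reduction; pH −0.6
  units and NO3-N +2 mg/kg under nitrogen addition) and per-plot noise.
  Six replicate plots per treatment × layer feed the ANOVA; their means,
  aligned to the community samples, feed the RDA — mirroring a design
  where replicate plots are pooled into one sequenced sample but
  chemistry is assayed per plot.
* **Taxonomy**: 150 OTUs over 30 phyla, with 80% of taxa (including all
  dominant ones) in 10 phyla so the top-10 summary carries >95% of the
  mass.

What the generator does **not** emulate: sequence-level artifacts
(chimeras, clustering errors), spatial autocorrelation between adjacent
layers, phylogenetic correlation of responses, overdispersion beyond the
latent log-normal, and rare-taxon detection limits. Passing tests
therefore demonstrate that the pipeline's statistics do what they claim
on data with known structure — not that any particular field inference is
correct, and not that real data meet these assumptions.

`generate_null_pair()` draws a community matrix and covariates from two
separate random streams for permutation-test calibration; on repeated
pairs the test's p-values are approximately uniform (checked by a
Kolmogorov–Smirnov test in the suite).

## Numerical conventions and degenerate inputs

* Exact-oracle agreement (Spearman, Zi/Pi, topology metrics, modularity
  of a returned partition) is asserted to 1e-12; projection-based RDA
  quantities to 1e-9 relative.
* Prevalence is a strict majority: with S samples a taxon needs presence
  in more than S/2 (4 of 6 kept, 3 of 6 dropped); the filter is
  idempotent.
* Thresholding is strict (|rho| > St); |rho| = St yields no edge.
* Degenerate cases error loudly rather than guess: all-zero samples in
  relative abundance, empty networks in metrics requiring edges, isolated
  nodes in Pi (they cannot occur after isolated-node removal), groups of
  one observation in ANOVA, constant Y or sub-99 permutation counts in
  the Monte Carlo test.
* All stochastic operations take a seed and restore the caller's RNG
  state; stage seeds inside the pipeline derive deterministically from
  the master seed.
* Tests and the acceptance script run at deliberately modest problem
  sizes — 150 taxa × 30 samples for pipeline-scale checks, ≤ 10-node
  graphs for exhaustive oracles (partition enumeration grows as the Bell
  numbers), 100–1000 null replicates, 99–999 permutations — sizes at
  which the exhaustive references are exact and the whole suite runs in
  well under a minute.

## Known limitations

* Spearman on 5 pooled samples per treatment (the no-replicate design)
  takes only coarse rank values; the pipeline warns below 10 samples but
  follows the design rather than second-guessing it.
* Greedy modularity is a heuristic; on adversarial graphs it can return
  Q below the optimum (tests bound it by the exhaustive maximum, they do
  not require equality except on planted structures).
* The published average-connectivity convention is not always exactly
  2L/N in comparable reports; this package defines it as 2L/N and says
  so, rather than reverse-engineering undocumented variants.
* No RMT threshold selection, no weighted or signed community detection,
  no CCA, no variance partitioning, no forward covariate selection.
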