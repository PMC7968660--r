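# Redundancy analysis of community composition against soil chemistry.

.apply_transform <- function(Y, transform) {
  switch(transform,
         none = Y,
         hellinger = vegan::decostand(Y, method = "hellinger"),
         log1p = log1p(Y),
         fail("unknown transform '%s'", transform))
}

.check_covariates <- function(X) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  sds <- apply(X, 2L, stats::sd)
  if (any(sds == 0)) {
    fail("constant covariate column(s): %s",
         paste(colnames(X)[sds == 0], collapse = ", "))
  }
  Xs <- scale(X)
  q <- qr(Xs)
  if (q$rank < ncol(Xs)) {
    fail("collinear covariate column(s): %s",
         paste(colnames(Xs)[q$pivot[(q$rank + 1L):ncol(Xs)]], collapse = ", "))
  }
  Xs
}

# Constrained inertia of centered Y projected on the column space of Xs;
# the permutation-test statistic, shared by observed and permuted fits.
.constrained_trace <- function(Yc, Xs) {
  fit <- qr.fitted(qr(Xs), Yc)
  sum(fit^2) / (nrow(Yc) - 1)
}

#' Redundancy analysis (RDA) of a community matrix on covariates
#'
#' Projects the (optionally transformed, column-centered) community matrix
#' onto the column space of the standardized covariates and
#' eigendecomposes the fitted values (via [vegan::rda()]).  Axis
#' importance is reported both as percent of the *total* community
#' variance and as percent of the *constrained* variance.
#'
#' The default species pre-transform is the Hellinger transform
#' (square-root of relative abundances), the usual choice for making
#' compositional count data amenable to the Euclidean geometry of RDA;
#' `"none"` and `"log1p"` are also available.
#'
#' @param Y Samples x taxa abundance matrix.
#' @param X Samples x covariates matrix or data.frame (same row order as
#'   `Y`); standardized internally, so results are invariant to the units
#'   of each covariate.
#' @param transform Species pre-transform: `"hellinger"` (default),
#'   `"none"`, or `"log1p"`.
#' @return List of class `"rda_result"`: `eig` (constrained eigenvalues,
#'   non-increasing), `pct_total` and `pct_constrained` (percent explained
#'   per axis), `trace` (constrained variance), `total` (total variance),
#'   `pct_unconstrained`, score matrices `site_scores`, `species_scores`,
#'   `biplot_scores`, and the underlying vegan object as `ord`.
#' @export
rda_fit <- function(Y, X, transform = c("hellinger", "none", "log1p")) {
  transform <- match.arg(transform)
  Y <- as.matrix(Y)
  X0 <- as.matrix(X)
  if (nrow(Y) != nrow(X0)) fail("Y and X must have the same samples (rows)")
  if (nrow(Y) <= ncol(X0) + 1L) fail("need more samples than covariates")
  Xs <- .check_covariates(X0)
  Yt <- .apply_transform(Y, transform)
  ord <- vegan::rda(Yt, Xs)
  eig <- ord$CCA$eig
  total <- ord$tot.chi
  trace <- ord$CCA$tot.chi
  k <- length(eig)
  structure(list(
    eig = eig,
    pct_total = 100 * eig / total,
    pct_constrained = 100 * eig / sum(eig),
    trace = trace,
    total = total,
    pct_unconstrained = 100 * (total - trace) / total,
    site_scores = vegan::scores(ord, display = "sites", choices = seq_len(k)),
    species_scores = vegan::scores(ord, display = "species", choices = seq_len(k)),
    biplot_scores = ord$CCA$biplot,
    transform = transform,
    ord = ord
  ), class = "rda_result")
}

#' @export
print.rda_result <- function(x, ...) {
  cat(sprintf("RDA (%s transform): constrained %.4g of total %.4g (%.2f%%)\n",
              x$transform, x$trace, x$total, 100 * x$trace / x$total))
  k <- min(length(x$eig), 4L)
  for (i in seq_len(k)) {
    cat(sprintf("  axis %d: %.2f%% of total (%.2f%% of constrained)\n",
                i, x$pct_total[i], x$pct_constrained[i]))
  }
  invisible(x)
}

#' Monte Carlo permutation test for the RDA constrained variance
#'
#' Permutes whole rows of the covariate matrix, recomputes the constrained
#' trace for each permutation, and reports the add-one p-value
#' `p = (1 + #\{perm >= observed\}) / (1 + n_perm)`, which is always
#' strictly positive.  Optionally permutes within strata (e.g. soil
#' layers).
#'
#' @inheritParams rda_fit
#' @param n_perm Number of permutations (>= 99; default 999).
#' @param seed Integer seed.
#' @param strata Optional factor of length `nrow(Y)`; permutations are
#'   then restricted to within-stratum row exchanges.
#' @return List of class `"permutation_test"`: `statistic` (observed
#'   constrained trace), `permuted` (numeric vector), `p_value`, `n_perm`,
#'   `seed`.
#' @export
monte_carlo_test <- function(Y, X, n_perm = 999, seed = NULL,
                             transform = c("hellinger", "none", "log1p"),
                             strata = NULL) {
  transform <- match.arg(transform)
  if (n_perm < 99L) fail("n_perm must be at least 99")
  Y <- as.matrix(Y)
  X0 <- as.matrix(X)
  if (nrow(Y) != nrow(X0)) fail("Y and X must have the same samples (rows)")
  Yc <- scale(.apply_transform(Y, transform), center = TRUE, scale = FALSE)
  if (all(abs(Yc) < .Machine$double.eps^0.5)) fail("Y is constant across samples")
  Xs <- .check_covariates(X0)
  n <- nrow(Yc)
  if (!is.null(strata) && length(strata) != n) fail("strata must match rows of Y")
  obs <- .constrained_trace(Yc, Xs)
  perm_idx <- function() {
    if (is.null(strata)) return(sample.int(n))
    idx <- seq_len(n)
    for (lv in split(seq_len(n), strata)) idx[lv] <- lv[sample.int(length(lv))]
    idx
  }
  permuted <- with_seed(seed, vapply(seq_len(n_perm), function(k) {
    .constrained_trace(Yc, Xs[perm_idx(), , drop = FALSE])
  }, numeric(1)))
  structure(list(
    statistic = obs,
    permuted = permuted,
    p_value = (1 + sum(permuted >= obs)) / (1 + n_perm),
    n_perm = n_perm,
    seed = seed
  ), class = "permutation_test")
}

#' @export
print.permutation_test <- function(x, ...) {
  cat(sprintf("Monte Carlo permutation test: trace = %.4g, p = %.4g (%d permutations)\n",
              x$statistic, x$p_value, x$n_perm))
  invisible(x)
}
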