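#' One-way ANOVA with Tukey HSD compact letter display
#'
#' Classical one-way analysis of variance across groups, followed by all
#' pairwise Tukey HSD comparisons at level `alpha`.  Groups are labelled
#' with compact letters (insert-and-absorb): two groups share a letter iff
#' their Tukey-adjusted p-value is at least `alpha` — the "different letters
#' in the same column indicate significant differences (P < 0.05)"
#' convention of soil-chemistry tables.
#'
#' @param values Named list of numeric vectors, one per group; at least two
#'   groups with at least two observations each.
#' @param alpha Significance level (default 0.05).
#' @return An object of class `"anova_oneway"`: list with `table`
#'   (data.frame of group, n, mean, se, letters), `F`, `p`, `alpha`,
#'   `tukey` (matrix of pairwise adjusted p-values).
#' @examples
#' set.seed(1)
#' anova_oneway(list(a = rnorm(6), b = rnorm(6), c = rnorm(6, 5)))
#' @export
anova_oneway <- function(values, alpha = 0.05) {
  if (!is.list(values) || length(values) < 2L) fail("need at least two groups")
  if (is.null(names(values)) || any(!nzchar(names(values)))) {
    names(values) <- paste0("g", seq_along(values))
  }
  sizes <- lengths(values)
  if (any(sizes < 2L)) {
    fail("group(s) with fewer than 2 observations: %s",
         paste(names(values)[sizes < 2L], collapse = ", "))
  }
  df <- data.frame(
    value = unlist(values, use.names = FALSE),
    group = factor(rep(names(values), sizes), levels = names(values))
  )
  fit <- stats::aov(value ~ group, data = df)
  an <- summary(fit)[[1L]]
  Fstat <- an[["F value"]][1L]
  pval <- an[["Pr(>F)"]][1L]
  tk <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$group
  # pairwise adjusted p matrix in level order
  lv <- levels(df$group)
  pmat <- matrix(NA_real_, length(lv), length(lv), dimnames = list(lv, lv))
  pairs <- strsplit(rownames(tk), "-", fixed = TRUE)
  for (k in seq_along(pairs)) {
    i <- pairs[[k]][1L]; j <- pairs[[k]][2L]
    pmat[i, j] <- pmat[j, i] <- tk[k, "p adj"]
  }
  letters_map <- compact_letters(lv, pmat, alpha)
  tab <- data.frame(
    group = lv,
    n = as.integer(sizes[lv]),
    mean = vapply(values[lv], mean, numeric(1)),
    se = vapply(values[lv], function(v) stats::sd(v) / sqrt(length(v)), numeric(1)),
    letters = letters_map[lv],
    row.names = NULL
  )
  structure(list(table = tab, F = Fstat, p = pval, alpha = alpha, tukey = pmat),
            class = "anova_oneway")
}

#' @export
print.anova_oneway <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F = %.4g, p = %.4g (alpha = %g)\n", x$F, x$p, x$alpha))
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Compact letter display by insert-and-absorb
#'
#' Starts with one letter column holding all groups and, for every
#' significantly different pair, splits any column containing both members;
#' redundant (subset) columns are absorbed.  The result guarantees: two
#' groups share a letter iff their pairwise p-value is `>= alpha`.
#'
#' @param groups Character vector of group names.
#' @param pmat Symmetric matrix of pairwise p-values (dimnames = groups).
#' @param alpha Significance level.
#' @return Named character vector of letter strings.
#' @export
compact_letters <- function(groups, pmat, alpha = 0.05) {
  cols <- list(groups)
  combs <- utils::combn(groups, 2L, simplify = FALSE)
  for (pr in combs) {
    if (is.na(pmat[pr[1L], pr[2L]]) || pmat[pr[1L], pr[2L]] >= alpha) next
    k <- 1L
    while (k <= length(cols)) {
      if (all(pr %in% cols[[k]])) {
        a <- setdiff(cols[[k]], pr[1L])
        b <- setdiff(cols[[k]], pr[2L])
        cols[[k]] <- a
        cols[[length(cols) + 1L]] <- b
      }
      k <- k + 1L
    }
    # absorb columns that are subsets of another
    keep <- rep(TRUE, length(cols))
    for (u in seq_along(cols)) {
      for (v in seq_along(cols)) {
        if (u == v || !keep[u] || !keep[v]) next
        if (all(cols[[u]] %in% cols[[v]]) &&
            (length(cols[[u]]) < length(cols[[v]]) || u > v)) {
          keep[u] <- FALSE
        }
      }
    }
    cols <- cols[keep]
  }
  # deterministic letter order: by first member's position in `groups`
  first_pos <- vapply(cols, function(cc) min(match(cc, groups)), numeric(1))
  cols <- cols[order(first_pos)]
  lab <- make_letter_labels(length(cols))
  out <- stats::setNames(rep("", length(groups)), groups)
  for (k in seq_along(cols)) {
    for (g in cols[[k]]) out[g] <- paste0(out[g], lab[k])
  }
  out
}

# a, b, ..., z, aa, ab, ... labels
make_letter_labels <- function(n) {
  if (n <= 26L) return(letters[seq_len(n)])
  c(letters, as.vector(outer(letters, letters, function(a, b) paste0(a, b))))[seq_len(n)]
}

#' Per-layer chemistry ANOVA table
#'
#' Runs [anova_oneway()] for every soil layer and chemistry variable across
#' treatments, using replicate-level chemistry observations, and returns a
#' long table mirroring the classic mean +/- SE + letters layout.
#'
#' @param chem_reps data.frame with `treatment`, `layer`, and the chemistry
#'   columns of [chemistry_variables()], one row per replicate plot.
#' @param alpha Significance level.
#' @return data.frame with layer, variable, treatment, n, mean, se,
#'   letters, F, p.
#' @export
chemistry_anova_table <- function(chem_reps, alpha = 0.05) {
  vars <- intersect(chemistry_variables(), names(chem_reps))
  if (!length(vars)) fail("no chemistry variable columns found")
  layers <- unique(as.character(chem_reps$layer))
  out <- list()
  for (ly in layers) {
    sub <- chem_reps[as.character(chem_reps$layer) == ly, , drop = FALSE]
    for (v in vars) {
      grps <- split(sub[[v]], as.character(sub$treatment))
      grps <- grps[unique(as.character(sub$treatment))]  # keep design order
      res <- anova_oneway(grps, alpha = alpha)
      tab <- res$table
      tab <- data.frame(layer = ly, variable = v, tab,
                        F = res$F, p = res$p, row.names = NULL)
      out[[length(out) + 1L]] <- tab
    }
  }
  do.call(rbind, out)
}
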