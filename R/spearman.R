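#' Spearman similarity matrix between taxa
#'
#' Pairwise Spearman rank correlation (Pearson correlation of mid-ranks,
#' ties averaged) between the abundance profiles of every pair of taxa
#' across samples.  Taxa whose profile is constant across samples have no
#' defined rank correlation; they are reported with rho = 0 against all
#' other taxa (with a warning) so they cannot form edges.  Being rank
#' based, the matrix is invariant under any strictly monotone transform of
#' a taxon's abundances.
#'
#' @param table A [count_table()] or plain numeric matrix, taxa in rows,
#'   samples in columns; at least 3 samples.
#' @return Symmetric matrix of Spearman rho in \[-1, 1\] with unit
#'   diagonal, dimnames = taxon ids.
#' @export
spearman_matrix <- function(table) {
  x <- unclass(table)
  if (!is.matrix(x)) fail("table must be a matrix")
  if (ncol(x) < 3L) fail("need at least 3 samples for rank correlation")
  constant <- apply(x, 1L, function(r) length(unique(r)) == 1L)
  if (any(constant)) {
    warning(sprintf("%d constant taxa get rho = 0 against all others: %s",
                    sum(constant),
                    paste(utils::head(rownames(x)[constant], 5L), collapse = ", ")),
            call. = FALSE)
  }
  rho <- suppressWarnings(stats::cor(t(x), method = "spearman"))
  rho[!is.finite(rho)] <- 0
  diag(rho) <- 1
  rho
}
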