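#' Shannon-Wiener diversity index
#'
#' H = -sum(p_i log p_i) over taxa with positive counts, with p_i the count
#' proportions.  Reported in nats (natural log) by default; the log base is
#' configurable.
#'
#' @param counts Non-negative numeric vector of taxon counts (or
#'   proportions; the index is scale-invariant).
#' @param base Logarithm base (default `exp(1)`, i.e. nats).
#' @return Numeric scalar, `0 <= H <= log(richness, base)`.
#' @examples
#' shannon_index(rep(5, 10))     # uniform over 10 taxa: log(10)
#' shannon_index(c(0, 0, 7))     # single taxon: 0
#' @export
shannon_index <- function(counts, base = exp(1)) {
  if (anyNA(counts) || any(counts < 0)) fail("counts must be non-negative")
  if (sum(counts) == 0) fail("all counts are zero")
  as.numeric(vegan::diversity(counts, index = "shannon", base = base))
}

#' Taxon richness
#'
#' Number of taxa with a positive count.
#'
#' @param counts Non-negative numeric vector.
#' @return Integer count.
#' @export
richness <- function(counts) {
  if (anyNA(counts) || any(counts < 0)) fail("counts must be non-negative")
  sum(counts > 0)
}

#' Relative percent change in relative abundance
#'
#' `100 * (p_treatment - p_control) / p_control`: the "+10.98%" style of
#' statement about a phylum's abundance shift under a treatment relative to
#' the control.  This is relative change, not a percentage-point difference.
#'
#' @param p_treatment,p_control Proportions (vectors recycle as usual);
#'   `p_control` must be strictly positive.
#' @return Percent change (positive = increase).
#' @export
relabund_change <- function(p_treatment, p_control) {
  if (any(p_control <= 0)) fail("p_control must be > 0")
  100 * (p_treatment - p_control) / p_control
}

#' Per-sample diversity table
#'
#' @param table A [count_table()].
#' @param base Log base for the Shannon index.
#' @return data.frame with `sample_id`, `shannon`, `richness`.
#' @export
diversity_table <- function(table, base = exp(1)) {
  x <- unclass(count_table(unclass(table)))
  data.frame(
    sample_id = colnames(x),
    shannon = apply(x, 2L, shannon_index, base = base),
    richness = apply(x, 2L, richness),
    row.names = NULL
  )
}
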