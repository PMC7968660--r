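#' Rarefy a count table to a fixed sequencing depth
#'
#' Subsamples each sample's reads without replacement (multivariate
#' hypergeometric, via [vegan::rrarefy()]) so that every retained column
#' sums exactly to `depth`.  Samples with fewer than `depth` reads cannot be
#' subsampled without replacement and are dropped with a warning.  The
#' default depth of 4269 reads per sample is the normalization depth used
#' throughout this pipeline.
#'
#' @param table A [count_table()].
#' @param depth Target reads per sample (positive integer).
#' @param seed Integer seed making the subsampling reproducible; `NULL`
#'   draws from the current RNG stream.
#' @return A [count_table()] with the retained samples, each summing to
#'   `depth`.  Taxa rows are kept even if they drop to all-zero.
#' @export
rarefy <- function(table, depth = 4269, seed = NULL) {
  x <- count_table(unclass(table))
  if (length(depth) != 1L || !is.finite(depth) || depth < 1 || depth != round(depth)) {
    fail("depth must be a positive integer")
  }
  depth <- as.integer(depth)
  totals <- colSums(x)
  drop <- totals < depth
  if (any(drop)) {
    warning(sprintf("dropping %d sample(s) with fewer than %d reads: %s",
                    sum(drop), depth,
                    paste(colnames(x)[drop], collapse = ", ")),
            call. = FALSE)
  }
  x <- x[, !drop, drop = FALSE]
  if (ncol(x) == 0L) fail("no sample reaches depth %d", depth)
  # muffle vegan's "smallest count" heuristic: inputs are validated
  # integer counts, zero-truncation is expected for abundant taxa
  out <- with_seed(seed, withCallingHandlers(
    vegan::rrarefy(t(unclass(x)), sample = depth),
    warning = function(w) {
      if (grepl("observed counts", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }))
  out <- t(out)
  storage.mode(out) <- "integer"
  count_table(out)
}

#' Retain taxa present in a strict majority of samples
#'
#' A taxon is kept iff its count is positive in more than half of all
#' samples (strictly greater than S/2).  With 6 samples, presence in 4 keeps
#' a taxon and presence in 3 drops it.  The filter is idempotent.
#'
#' @param table A [count_table()].
#' @return Filtered [count_table()].
#' @export
prevalence_filter <- function(table) {
  x <- count_table(unclass(table))
  if (ncol(x) == 0L || nrow(x) == 0L) fail("count table is empty")
  keep <- rowSums(unclass(x) > 0L) > ncol(x) / 2
  count_table(unclass(x)[keep, , drop = FALSE])
}

#' Aggregate taxon counts to phylum level
#'
#' Sums the counts of all taxa mapped to the same phylum; per-sample totals
#' are conserved exactly.  Every taxon in the table must be covered by the
#' taxonomy map.
#'
#' @param table A [count_table()].
#' @param taxonomy Named character vector (taxon id -> phylum), as returned
#'   by [read_taxonomy()].
#' @return A [count_table()] whose rows are phyla, in order of first
#'   appearance.
#' @export
aggregate_to_phylum <- function(table, taxonomy) {
  x <- count_table(unclass(table))
  missing <- setdiff(rownames(x), names(taxonomy))
  if (length(missing)) {
    fail("taxa missing from taxonomy map: %s", paste(missing, collapse = ", "))
  }
  grp <- unname(taxonomy[rownames(x)])
  out <- rowsum(unclass(x), group = grp, reorder = FALSE)
  storage.mode(out) <- "integer"
  count_table(out)
}

#' Per-sample relative abundances
#'
#' @param table A [count_table()].
#' @return Numeric matrix of proportions; every column sums to 1.
#' @export
relative_abundance <- function(table) {
  x <- unclass(count_table(unclass(table)))
  cs <- colSums(x)
  if (any(cs == 0)) {
    fail("sample(s) with zero total count: %s",
         paste(colnames(x)[cs == 0], collapse = ", "))
  }
  sweep(x, 2L, cs, "/")
}

#' Summarize proportions as the top taxa plus a pooled remainder
#'
#' Keeps the `n_top` rows with the highest overall mean proportion and pools
#' everything else into a final `"others"` row — the usual top-10-phyla
#' presentation of community composition, under which the dominant phyla
#' typically carry well over 95% of the community.
#'
#' @param rel Proportion matrix from [relative_abundance()].
#' @param n_top Number of taxa kept individually (default 10).
#' @param others_label Label for the pooled remainder row.
#' @return Proportion matrix with at most `n_top + 1` rows; columns still
#'   sum to 1.
#' @export
top_taxa_summary <- function(rel, n_top = 10, others_label = "others") {
  if (nrow(rel) <= n_top) return(rel)
  ord <- order(rowMeans(rel), decreasing = TRUE)
  top <- rel[ord[seq_len(n_top)], , drop = FALSE]
  rest <- rel[ord[-seq_len(n_top)], , drop = FALSE]
  out <- rbind(top, colSums(rest))
  rownames(out)[nrow(out)] <- others_label
  out
}
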