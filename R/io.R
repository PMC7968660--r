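#' Validate a taxon-by-sample count matrix
#'
#' A count table is a non-negative integer matrix with taxa as rows and
#' samples as columns, both carrying unique identifiers in the dimnames.
#' This is the object every preprocessing and network stage consumes.
#'
#' @param counts Numeric matrix, taxa in rows, samples in columns, with
#'   `rownames` (taxon ids) and `colnames` (sample ids).
#' @return The validated matrix (integer storage) with class
#'   `"count_table"` prepended.
#' @examples
#' m <- matrix(c(0L, 3L, 5L, 2L, 1L, 0L), nrow = 3,
#'             dimnames = list(c("t1", "t2", "t3"), c("s1", "s2")))
#' ct <- count_table(m)
#' dim(ct)
#' @export
count_table <- function(counts) {
  if (!is.matrix(counts)) fail("counts must be a matrix")
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    fail("count table must have taxon rownames and sample colnames")
  }
  dup_t <- unique(rownames(counts)[duplicated(rownames(counts))])
  if (length(dup_t)) fail("duplicated taxon id(s): %s", paste(dup_t, collapse = ", "))
  dup_s <- unique(colnames(counts)[duplicated(colnames(counts))])
  if (length(dup_s)) fail("duplicated sample id(s): %s", paste(dup_s, collapse = ", "))
  if (anyNA(counts)) fail("count table contains missing values")
  if (any(counts < 0)) {
    bad <- which(counts < 0, arr.ind = TRUE)[1, ]
    fail("negative count at taxon '%s', sample '%s'",
         rownames(counts)[bad[1]], colnames(counts)[bad[2]])
  }
  if (any(counts != round(counts))) {
    bad <- which(counts != round(counts), arr.ind = TRUE)[1, ]
    fail("non-integer count at taxon '%s', sample '%s'",
         rownames(counts)[bad[1]], colnames(counts)[bad[2]])
  }
  storage.mode(counts) <- "integer"
  class(counts) <- c("count_table", class(counts))
  counts
}

#' @export
print.count_table <- function(x, ...) {
  cat(sprintf("count_table: %d taxa x %d samples, %s reads total\n",
              nrow(x), ncol(x), format(sum(as.numeric(x)), big.mark = ",")))
  invisible(x)
}

# Split non-comment TSV lines into fields; used by the count-table reader so
# validation errors can name the offending cell.
.tsv_lines <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines)]
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2L) fail("file '%s' has no data rows", path)
  strsplit(lines, "\t", fixed = TRUE)
}

#' Read a taxon-by-sample count table from TSV
#'
#' Expects a header row of sample ids (first header cell arbitrary), one row
#' per taxon with the taxon id in the first column, tab-delimited integer
#' cells, UTF-8, with `#` comment lines ignored.
#'
#' @param path Path to a TSV file.
#' @return A [count_table()].
#' @seealso [write_count_table()]
#' @export
read_count_table <- function(path) {
  fields <- .tsv_lines(path)
  header <- fields[[1L]]
  sample_ids <- header[-1L]
  if (length(sample_ids) < 1L) fail("header of '%s' names no samples", path)
  dup <- unique(sample_ids[duplicated(sample_ids)])
  if (length(dup)) fail("duplicated sample id(s) in header: %s", paste(dup, collapse = ", "))
  body <- fields[-1L]
  n_col <- length(header)
  taxon_ids <- character(length(body))
  counts <- matrix(0L, nrow = length(body), ncol = length(sample_ids))
  for (i in seq_along(body)) {
    row <- body[[i]]
    if (length(row) != n_col) {
      fail("row %d ('%s') has %d fields, expected %d", i, row[1L], length(row), n_col)
    }
    taxon_ids[i] <- row[1L]
    vals <- suppressWarnings(as.numeric(row[-1L]))
    if (anyNA(vals)) {
      j <- which(is.na(vals))[1L]
      fail("non-numeric cell at taxon '%s', sample '%s': '%s'",
           row[1L], sample_ids[j], row[j + 1L])
    }
    counts[i, ] <- vals
  }
  rownames(counts) <- taxon_ids
  colnames(counts) <- sample_ids
  count_table(counts)
}

#' Write a count table to TSV
#'
#' @param table A [count_table()] (or plain matrix with dimnames).
#' @param path Output path.
#' @param id_col Name for the leading taxon-id column.
#' @return `path`, invisibly.
#' @export
write_count_table <- function(table, path, id_col = "taxon_id") {
  m <- unclass(table)
  df <- data.frame(id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1L] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

# Shared TSV reader for metadata-like tables.  na.strings = "" so the literal
# treatment label "NA" (nitrogen addition) survives as a string.
.read_tsv <- function(path, required) {
  df <- utils::read.delim(path, sep = "\t", comment.char = "#",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          na.strings = "")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    fail("file '%s' lacks required column(s): %s", path,
         paste(missing, collapse = ", "))
  }
  df
}

#' Read a taxon-to-phylum taxonomy map from TSV
#'
#' Two required columns: `taxon_id` and `phylum`.  Taxa without an assignment
#' may use any reserved label (e.g. `"unassigned"`); the value is treated as
#' an opaque phylum name.
#'
#' @param path Path to a TSV file.
#' @return Named character vector mapping taxon id to phylum.
#' @export
read_taxonomy <- function(path) {
  df <- .read_tsv(path, c("taxon_id", "phylum"))
  dup <- unique(df$taxon_id[duplicated(df$taxon_id)])
  if (length(dup)) fail("duplicated taxon id(s) in taxonomy: %s", paste(dup, collapse = ", "))
  stats::setNames(as.character(df$phylum), df$taxon_id)
}

#' Write a taxonomy map to TSV
#' @param taxonomy Named character vector (taxon id -> phylum).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_taxonomy <- function(taxonomy, path) {
  utils::write.table(
    data.frame(taxon_id = names(taxonomy), phylum = unname(taxonomy)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read per-sample metadata from TSV
#'
#' Required columns: `sample_id`, `treatment`, `layer`, `replicate`.
#' Treatments must come from the six-level design (CK, WA, WR, NA, NAWA,
#' NAWR by default) and layers from the five depth bins.
#'
#' @param path Path to a TSV file.
#' @param treatments,layers Allowed level sets (closed enums).
#' @return data.frame with factor `treatment` and `layer` columns.
#' @export
read_sample_metadata <- function(path,
                                 treatments = steppenet_treatments(),
                                 layers = steppenet_layers()) {
  df <- .read_tsv(path, c("sample_id", "treatment", "layer", "replicate"))
  validate_sample_metadata(df, treatments = treatments, layers = layers)
}

#' Validate a sample-metadata data.frame
#' @param df data.frame with `sample_id`, `treatment`, `layer`, `replicate`.
#' @inheritParams read_sample_metadata
#' @return The validated data.frame with factor treatment/layer.
#' @export
validate_sample_metadata <- function(df,
                                     treatments = steppenet_treatments(),
                                     layers = steppenet_layers()) {
  dup <- unique(df$sample_id[duplicated(df$sample_id)])
  if (length(dup)) fail("duplicated sample id(s): %s", paste(dup, collapse = ", "))
  bad_t <- setdiff(unique(df$treatment), treatments)
  if (length(bad_t)) fail("unknown treatment level(s): %s", paste(bad_t, collapse = ", "))
  bad_l <- setdiff(unique(df$layer), layers)
  if (length(bad_l)) fail("unknown soil layer(s): %s", paste(bad_l, collapse = ", "))
  df$treatment <- factor(df$treatment, levels = treatments)
  df$layer <- factor(df$layer, levels = layers)
  df$replicate <- as.integer(df$replicate)
  df
}

#' Read a soil-chemistry table from TSV
#'
#' Required columns: `sample_id`, `pH`, `moisture`, `TC`, `TN`, `NO3N`,
#' `NH4N` (moisture/TC/TN in percent, nitrogen pools in mg/kg).  Values must
#' be complete; moisture, TC and TN must be non-negative.
#'
#' @param path Path to a TSV file.
#' @return data.frame keyed by `sample_id`.
#' @export
read_chemistry <- function(path) {
  df <- .read_tsv(path, c("sample_id", chemistry_variables()))
  validate_chemistry(df)
}

#' Validate a soil-chemistry data.frame
#' @param df data.frame with `sample_id` plus the six chemistry columns.
#' @return The validated data.frame.
#' @export
validate_chemistry <- function(df) {
  vars <- chemistry_variables()
  for (v in vars) {
    if (anyNA(df[[v]])) fail("chemistry column '%s' has missing values", v)
    df[[v]] <- as.numeric(df[[v]])
  }
  for (v in c("moisture", "TC", "TN")) {
    if (any(df[[v]] < 0)) fail("chemistry column '%s' has negative values", v)
  }
  df
}

#' Write a data.frame to TSV (tab-delimited, unquoted, no row names)
#' @param df data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' The six experimental treatments
#'
#' Control (CK), water addition (WA), water reduction (WR), nitrogen
#' addition (NA), and the two combined regimes (NAWA, NAWR).
#' @return Character vector of treatment codes.
#' @export
steppenet_treatments <- function() c("CK", "WA", "WR", "NA", "NAWA", "NAWR")

#' The five soil depth bins (cm)
#' @return Character vector of layer labels.
#' @export
steppenet_layers <- function() c("0-2", "2-5", "5-10", "10-20", "20-30")

#' The six soil-chemistry variables
#' @return Character vector of column names.
#' @export
chemistry_variables <- function() c("pH", "moisture", "TC", "TN", "NO3N", "NH4N")
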