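#' Feature-by-sample count container
#'
#' A lightweight container for amplicon/metagenome feature tables: a
#' non-negative integer matrix (features in rows, samples in columns), a
#' per-sample metadata tibble and an optional per-feature taxonomy tibble.
#' All analysis functions in the package accept either a `rhizo_counts`
#' object or a plain matrix.
#'
#' @param counts Non-negative integer matrix with feature IDs as rownames and
#'   sample IDs as colnames.
#' @param metadata Data frame with one row per sample; must contain
#'   `sample_id` covering every column of `counts`. Conventional columns are
#'   `community` (e.g. `soil_wash`, `cycle_1` ... `cycle_6`, `sbrb`,
#'   `recovered`), `cycle` (integer or NA) and `replicate`.
#' @param taxonomy Optional data frame with `feature_id` and `lineage`
#'   (a single `;`-separated taxonomy string) or rank columns.
#'
#' @return An object of class `rhizo_counts` (a list with elements `counts`,
#'   `metadata`, `taxonomy`).
#' @examples
#' m <- matrix(c(5L, 0L, 3L, 2L), 2, 2,
#'   dimnames = list(c("ASV1", "ASV2"), c("s1", "s2")))
#' rc <- rhizo_counts(m, data.frame(sample_id = c("s1", "s2"),
#'   community = "cycle_1", cycle = 1, replicate = 1:2))
#' dim(rc)
#' @export
rhizo_counts <- function(counts, metadata, taxonomy = NULL) {
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    abort("`counts` must have feature rownames and sample colnames.")
  }
  if (anyDuplicated(rownames(counts))) abort("Duplicate feature IDs in `counts`.")
  if (anyDuplicated(colnames(counts))) abort("Duplicate sample IDs in `counts`.")
  if (any(is.na(counts))) abort("`counts` contains missing values.")
  if (any(counts < 0)) abort("`counts` contains negative values.")
  if (any(counts != round(counts))) abort("`counts` must be whole numbers.")
  storage.mode(counts) <- "integer"
  metadata <- as_tibble(metadata)
  if (!"sample_id" %in% names(metadata)) abort("`metadata` needs a `sample_id` column.")
  missing <- setdiff(colnames(counts), metadata$sample_id)
  if (length(missing) > 0) {
    abort(paste0("Metadata missing for sample(s): ", paste(missing, collapse = ", ")))
  }
  metadata <- metadata[match(colnames(counts), metadata$sample_id), , drop = FALSE]
  if (!is.null(taxonomy)) {
    taxonomy <- as_tibble(taxonomy)
    if (!"feature_id" %in% names(taxonomy)) {
      abort("`taxonomy` needs a `feature_id` column.")
    }
  }
  structure(list(counts = counts, metadata = metadata, taxonomy = taxonomy),
            class = "rhizo_counts")
}

#' @export
dim.rhizo_counts <- function(x) dim(x$counts)

#' @export
print.rhizo_counts <- function(x, ...) {
  cat(sprintf("<rhizo_counts> %d features x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  if ("community" %in% names(x$metadata)) {
    tab <- table(x$metadata$community)
    cat("communities:", paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
`[.rhizo_counts` <- function(x, i, j, ...) {
  counts <- x$counts[i, j, drop = FALSE]
  taxonomy <- x$taxonomy
  if (!is.null(taxonomy)) {
    taxonomy <- taxonomy[taxonomy$feature_id %in% rownames(counts), , drop = FALSE]
  }
  rhizo_counts(counts, x$metadata[x$metadata$sample_id %in% colnames(counts), ],
               taxonomy)
}

#' Tidy a count container into a long tibble
#'
#' @param x A [rhizo_counts] object.
#' @param ... Unused.
#' @return A tibble with one row per (feature, sample) pair, joined to the
#'   sample metadata.
#' @exportS3Method generics::tidy
tidy.rhizo_counts <- function(x, ...) {
  long <- as_tibble(as.data.frame.table(x$counts, stringsAsFactors = FALSE))
  names(long) <- c("feature_id", "sample_id", "count")
  left_join(long, x$metadata, by = "sample_id")
}

# Internal: coerce rhizo_counts or matrix to a plain numeric matrix.
count_matrix <- function(x) {
  if (inherits(x, "rhizo_counts")) x$counts else as.matrix(x)
}

# Internal: subset samples of a rhizo_counts by community label(s).
subset_community <- function(x, communities) {
  keep <- x$metadata$sample_id[x$metadata$community %in% communities]
  if (length(keep) == 0) {
    abort(paste0("No samples with community in: ", paste(communities, collapse = ", ")))
  }
  x[, keep]
}
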