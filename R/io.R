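#' Read and write feature count tables
#'
#' Tables are tab-separated plain text with feature IDs in the first column
#' and sample IDs as the header row. Metadata is a TSV with at least a
#' `sample_id` column.
#'
#' @param path Path to the count TSV.
#' @param metadata_path Path to the sample metadata TSV.
#' @param taxonomy_path Optional path to a taxonomy TSV (`feature_id`,
#'   `lineage`).
#' @return A [rhizo_counts] object.
#' @export
read_count_table <- function(path, metadata_path, taxonomy_path = NULL) {
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (ncol(raw) < 2) abort("Count table needs a feature-ID column plus >= 1 sample.")
  ids <- as.character(raw[[1]])
  m <- as.matrix(raw[, -1, drop = FALSE])
  if (!is.numeric(m)) abort("Count table has non-numeric cells.")
  bad <- which(is.na(m) | m < 0 | m != round(m), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    abort(sprintf("Count table cell (%s, %s) is not a non-negative integer.",
                  ids[bad[1, 1]], colnames(m)[bad[1, 2]]))
  }
  rownames(m) <- ids
  meta <- readr::read_tsv(metadata_path, show_col_types = FALSE, progress = FALSE)
  tax <- if (!is.null(taxonomy_path)) {
    readr::read_tsv(taxonomy_path, show_col_types = FALSE, progress = FALSE)
  }
  rhizo_counts(m, meta, tax)
}

#' @param x A [rhizo_counts] object (or matrix for `write_matrix_tsv`).
#' @param dir Directory to write into (created if needed).
#' @param prefix File-name prefix; writes `<prefix>_counts.tsv`,
#'   `<prefix>_metadata.tsv` and, when taxonomy is present,
#'   `<prefix>_taxonomy.tsv`.
#' @return `write_count_table()` invisibly returns the paths written.
#' @rdname read_count_table
#' @export
write_count_table <- function(x, dir, prefix = "feature") {
  stopifnot(inherits(x, "rhizo_counts"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(counts = file.path(dir, paste0(prefix, "_counts.tsv")),
             metadata = file.path(dir, paste0(prefix, "_metadata.tsv")))
  write_matrix_tsv(x$counts, paths[["counts"]])
  readr::write_tsv(x$metadata, paths[["metadata"]], progress = FALSE)
  if (!is.null(x$taxonomy)) {
    paths[["taxonomy"]] <- file.path(dir, paste0(prefix, "_taxonomy.tsv"))
    readr::write_tsv(x$taxonomy, paths[["taxonomy"]], progress = FALSE)
  }
  invisible(paths)
}

#' @param m A matrix with row and column names.
#' @param path Output path.
#' @param id_col Name for the first (row-ID) column.
#' @rdname read_count_table
#' @export
write_matrix_tsv <- function(m, path, id_col = "feature_id") {
  df <- as.data.frame(m, check.names = FALSE)
  df <- cbind(setNames(data.frame(rownames(m), stringsAsFactors = FALSE), id_col), df)
  readr::write_tsv(as_tibble(df), path, progress = FALSE)
  invisible(path)
}

#' Read and write DNA sequences (FASTA)
#'
#' Sequences are uppercased on read and `U` is mapped to `T`; any letter
#' outside `ACGT` is rejected so that downstream exact matching operates on a
#' canonical alphabet.
#'
#' @param path FASTA path.
#' @return `read_fasta()`: a named character vector (ID -> sequence).
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) {
    abort(paste0("Duplicate FASTA IDs: ",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  seqs <- toupper(as.character(set))
  seqs <- gsub("U", "T", seqs, fixed = TRUE)
  bad <- grepl("[^ACGT]", seqs)
  if (any(bad)) {
    abort(paste0("Non-ACGT/U characters in sequence(s): ",
                 paste(ids[bad][seq_len(min(3, sum(bad)))], collapse = ", ")))
  }
  setNames(seqs, ids)
}

#' @param sequences Named character vector of DNA sequences.
#' @rdname read_fasta
#' @export
write_fasta <- function(sequences, path) {
  set <- Biostrings::DNAStringSet(sequences)
  Biostrings::writeXStringSet(set, path, width = 80L)
  invisible(path)
}

#' Read and write phylogenies (Newick)
#'
#' Thin wrappers around \pkg{ape} that enforce the package's requirements:
#' trees used for Faith's PD must carry branch lengths, and when a count
#' table is supplied every feature must be a tip of the tree.
#'
#' @param path Newick path.
#' @param require_branch_lengths Error when the tree lacks branch lengths.
#' @param feature_ids Optional character vector; error listing the missing
#'   tips when any `feature_ids` are absent from the tree.
#' @return `read_newick()`: an [ape::phylo] object.
#' @export
read_newick <- function(path, require_branch_lengths = TRUE, feature_ids = NULL) {
  tree <- ape::read.tree(path)
  if (is.null(tree)) abort("Could not parse Newick file.")
  if (require_branch_lengths && is.null(tree$edge.length)) {
    abort("Tree has no branch lengths (required for Faith's PD).")
  }
  if (!is.null(feature_ids)) {
    missing <- setdiff(feature_ids, tree$tip.label)
    if (length(missing) > 0) {
      abort(paste0("Tips absent from tree: ",
                   paste(head(missing, 10), collapse = ", ")))
    }
  }
  tree
}

#' @param tree An [ape::phylo] object.
#' @rdname read_newick
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Read and write MAG tables
#'
#' The on-disk MAG table is a TSV with columns `mag_id`, `completeness`,
#' `contamination`, optional `strain_heterogeneity`, `taxonomy`,
#' `tpm_rhizcom`, `tpm_sbrb`, `tpm_soil`, and `reactions` (comma-separated
#' KEGG reaction IDs); any additional numeric columns (e.g. per-category
#' annotation counts) are carried through.
#'
#' @param path TSV path.
#' @return A tibble with `reactions` as a list-column of character vectors.
#' @export
read_mag_table <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("mag_id", "completeness", "contamination",
            "tpm_rhizcom", "tpm_sbrb", "tpm_soil", "reactions")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0) {
    abort(paste0("MAG table missing column(s): ", paste(missing, collapse = ", ")))
  }
  if (any(df$completeness < 0 | df$completeness > 100)) {
    abort("`completeness` must be in [0, 100].")
  }
  if (any(df$contamination < 0)) abort("`contamination` must be >= 0.")
  df$reactions <- strsplit(ifelse(is.na(df$reactions), "", df$reactions), ",", fixed = TRUE)
  df$reactions <- map(df$reactions, \(r) sort(unique(trimws(r[nzchar(r)]))))
  df
}

#' @param mags A MAG tibble as returned by [read_mag_table()] or
#'   [generate_mag_dataset()].
#' @rdname read_mag_table
#' @export
write_mag_table <- function(mags, path) {
  out <- mags
  out$reactions <- map_chr(out$reactions, paste, collapse = ",")
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Read and write co-culture growth tables
#'
#' Growth tables are TSVs with columns `strains` (one strain ID, or two
#' joined by `+` for co-cultures), `focal_strain`, `carbon_source`
#' (including `none` for the no-carbon controls), `replicate` and `cfu`.
#'
#' @param path TSV path.
#' @return A tibble.
#' @export
read_growth_table <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("strains", "focal_strain", "carbon_source", "replicate", "cfu")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0) {
    abort(paste0("Growth table missing column(s): ", paste(missing, collapse = ", ")))
  }
  if (any(df$cfu < 0)) abort("`cfu` must be >= 0.")
  df
}

#' @param records Growth tibble.
#' @rdname read_growth_table
#' @export
write_growth_table <- function(records, path) {
  readr::write_tsv(records, path, progress = FALSE)
  invisible(path)
}
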