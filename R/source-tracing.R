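#' Prevalence and lineage filtering of features
#'
#' Removes features whose taxonomy lineage contains any excluded term
#' (case-insensitive; e.g. mitochondria, chloroplast) and features whose
#' prevalence (fraction of samples with a nonzero count) is strictly below
#' `prevalence_min`.
#'
#' @param x A [rhizo_counts].
#' @param prevalence_min Minimum prevalence (default 0.05); features with
#'   prevalence `< prevalence_min` are removed.
#' @param excluded_lineages Character terms excluded by lineage match.
#' @return The filtered [rhizo_counts], with attribute `removed` (tibble
#'   `feature_id`, `reason`).
#' @export
filter_features <- function(x, prevalence_min = 0.05,
                            excluded_lineages = c("Mitochondria", "Chloroplast")) {
  stopifnot(inherits(x, "rhizo_counts"))
  m <- x$counts
  removed <- list()
  lineage_hit <- rep(FALSE, nrow(m))
  if (length(excluded_lineages) > 0 && !is.null(x$taxonomy) &&
      "lineage" %in% names(x$taxonomy)) {
    lin <- x$taxonomy$lineage[match(rownames(m), x$taxonomy$feature_id)]
    lin[is.na(lin)] <- ""
    pattern <- paste(excluded_lineages, collapse = "|")
    lineage_hit <- grepl(pattern, lin, ignore.case = TRUE)
    if (any(lineage_hit)) {
      removed$lineage <- tibble(feature_id = rownames(m)[lineage_hit],
                                reason = "excluded_lineage")
    }
  }
  prevalence <- rowMeans(m > 0)
  low_prev <- prevalence < prevalence_min & !lineage_hit
  if (any(low_prev)) {
    removed$prevalence <- tibble(feature_id = rownames(m)[low_prev],
                                 reason = "low_prevalence")
  }
  keep <- !(lineage_hit | low_prev)
  out <- x[keep, seq_len(ncol(m))]
  attr(out, "removed") <- bind_rows(removed) %||%
    tibble(feature_id = character(), reason = character())
  out
}

#' Exact full-length sequence matching
#'
#' A query matches a reference if and only if the full-length sequences are
#' identical; no mismatch tolerance. Duplicate sequences within either set
#' make identity ambiguous and are rejected.
#'
#' @param query,reference Named character vectors (ID -> sequence).
#' @return A tibble `query_id`, `reference_id` (NA when unmatched).
#' @export
match_exact <- function(query, reference) {
  for (nm in c("query", "reference")) {
    s <- if (nm == "query") query else reference
    if (anyDuplicated(s)) {
      abort(paste0("Duplicate sequences within the ", nm,
                   " set make exact identity ambiguous."))
    }
  }
  idx <- match(query, reference)
  tibble(query_id = names(query),
         reference_id = ifelse(is.na(idx), NA_character_, names(reference)[idx]))
}

#' Trace community members to their source communities
#'
#' Labels every feature of the sink community (RhizCom) by its presence in
#' the two possible sources: the soil wash and the seed-borne (SbRB)
#' community. Presence in a community is a nonzero mean abundance across its
#' replicates (for non-negative abundances the `mean` and `any` readings
#' coincide; both are accepted for interface compatibility). When
#' `sequences` is supplied, features are linked across tables by exact
#' full-length sequence matching rather than by shared IDs.
#'
#' The summary reports (a) the combined sink relative abundance carried by
#' each label, and (b) for each source community, the share of that source's
#' own relative abundance carried by features that also occur in the sink.
#'
#' @param rhizcom,soil,sbrb Abundance matrices (features x replicates), e.g.
#'   CSS-normalized; all filtered and normalized consistently.
#' @param sequences Optional named sequence vector covering the features of
#'   all three tables (IDs as names) for exact-match linking.
#' @param presence `"mean"` (default) or `"any"`.
#' @return A list of class `source_assignment`: `$assignments` (tibble
#'   `asv_id`, `label` in soil_only/sbrb_only/shared/untraced,
#'   `rel_abund_rhizcom`, `rel_abund_soil`, `rel_abund_sbrb`), `$summary`
#'   (per-label feature counts and combined relative abundance),
#'   `$source_contribution` (tibble `source`, `share`).
#' @export
classify_sources <- function(rhizcom, soil, sbrb, sequences = NULL,
                             presence = c("mean", "any")) {
  presence <- match.arg(presence)
  rhizcom <- count_matrix(rhizcom); soil <- count_matrix(soil); sbrb <- count_matrix(sbrb)
  present <- function(m) {
    if (presence == "mean") rowMeans(m) > 0 else apply(m > 0, 1, any)
  }
  # the sink universe is the features detected in the sink community
  rhizcom <- rhizcom[present(rhizcom), , drop = FALSE]
  if (nrow(rhizcom) == 0) abort("No features detected in the sink community.")
  link <- function(source_m) {
    if (is.null(sequences)) {
      match(rownames(rhizcom), rownames(source_m))
    } else {
      need <- unique(c(rownames(rhizcom), rownames(source_m)))
      miss <- setdiff(need, names(sequences))
      if (length(miss) > 0) {
        abort(paste0("`sequences` lacks feature(s): ",
                     paste(head(miss, 5), collapse = ", ")))
      }
      mm <- match_exact(sequences[rownames(rhizcom)], sequences[rownames(source_m)])
      match(mm$reference_id, rownames(source_m))
    }
  }
  soil_idx <- link(soil)
  sbrb_idx <- link(sbrb)
  soil_present <- present(soil)
  sbrb_present <- present(sbrb)
  in_soil <- !is.na(soil_idx) & soil_present[ifelse(is.na(soil_idx), 1L, soil_idx)]
  in_sbrb <- !is.na(sbrb_idx) & sbrb_present[ifelse(is.na(sbrb_idx), 1L, sbrb_idx)]
  label <- dplyr::case_when(in_soil & in_sbrb ~ "shared",
                            in_soil ~ "soil_only",
                            in_sbrb ~ "sbrb_only",
                            TRUE ~ "untraced")

  rel <- function(m) {
    mm <- rowMeans(m)
    mm / sum(mm)
  }
  rel_rhiz <- rel(rhizcom)
  rel_soil_all <- rel(soil)
  rel_sbrb_all <- rel(sbrb)
  assignments <- tibble(
    asv_id = rownames(rhizcom), label = label,
    rel_abund_rhizcom = unname(rel_rhiz),
    rel_abund_soil = ifelse(is.na(soil_idx), NA_real_, rel_soil_all[soil_idx]),
    rel_abund_sbrb = ifelse(is.na(sbrb_idx), NA_real_, rel_sbrb_all[sbrb_idx]))
  summary <- assignments |>
    mutate(label = factor(.data$label, levels = c("soil_only", "sbrb_only",
                                                  "shared", "untraced"))) |>
    group_by(label = .data$label, .drop = FALSE) |>
    summarise(n_features = dplyr::n(),
              rel_abund = sum(.data$rel_abund_rhizcom), .groups = "drop") |>
    mutate(label = as.character(.data$label))

  rhiz_detected <- rowMeans(rhizcom) > 0
  share_of_source <- function(source_m, idx) {
    # share of the source's relative abundance carried by features that are
    # detected in the sink
    hit <- rep(FALSE, nrow(source_m))
    ok <- !is.na(idx) & rhiz_detected
    hit[idx[ok]] <- TRUE
    rel_src <- rel(source_m)
    sum(rel_src[hit & present(source_m)])
  }
  contribution <- tibble(
    source = c("soil", "sbrb"),
    share = c(share_of_source(soil, soil_idx), share_of_source(sbrb, sbrb_idx)))
  structure(list(assignments = assignments, summary = summary,
                 source_contribution = contribution),
            class = "source_assignment")
}

#' @export
print.source_assignment <- function(x, ...) {
  cat("<source_assignment>\n")
  s <- x$summary
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-10s %4d features, %5.1f%% of sink abundance\n",
                s$label[i], s$n_features[i], 100 * s$rel_abund[i]))
  }
  invisible(x)
}

#' Tidy source assignments
#' @param x A `source_assignment`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.source_assignment <- function(x, ...) x$assignments

#' Summarise source tracing
#' @param x A `source_assignment`.
#' @param ... Unused.
#' @exportS3Method generics::glance
glance.source_assignment <- function(x, ...) {
  wide <- tidyr::pivot_wider(x$summary, names_from = "label",
                             values_from = c("n_features", "rel_abund"))
  dplyr::bind_cols(wide, tidyr::pivot_wider(x$source_contribution,
                                            names_from = "source",
                                            values_from = "share",
                                            names_prefix = "source_share_"))
}

#' Feature emergence curves across succession cycles
#'
#' For each relative-abundance threshold, a feature is detected at a cycle
#' if its mean (over replicates) relative abundance is `>= threshold`; it is
#' new at the first cycle at which it is detected. The inoculum (soil wash)
#' is conventionally included as cycle 0, so features present in the
#' inoculum do not count as emerging later; set `include_baseline = FALSE`
#' to start at the first table.
#'
#' @param cycle_tables Ordered named list of abundance matrices (features x
#'   replicates), cycle 0 (soil wash) first.
#' @param thresholds Numeric vector of relative-abundance cutoffs.
#' @param include_baseline Keep the first table (the inoculum) as cycle 0
#'   (default). With `FALSE` the first table is dropped and emergence is
#'   counted from the first propagation cycle onwards.
#' @return A tibble of class `emergence_curves`: `threshold`, `cycle_index`
#'   (0-based), `cycle_label`, `n_new`.
#' @export
emergence_curves <- function(cycle_tables, thresholds,
                             include_baseline = TRUE) {
  if (length(thresholds) == 0) abort("`thresholds` must be non-empty.")
  if (length(cycle_tables) == 0) abort("`cycle_tables` must be non-empty.")
  if (!include_baseline && length(cycle_tables) > 1) {
    cycle_tables <- cycle_tables[-1]
  }
  labels <- names(cycle_tables) %||% paste0("cycle_", seq_along(cycle_tables) - 1L)
  # mean relative abundance per feature per cycle, on the union feature set
  all_feats <- unique(unlist(lapply(cycle_tables, rownames)))
  mean_rel <- vapply(cycle_tables, function(m) {
    m <- count_matrix(m)
    rel <- sweep(m, 2, colSums(m), "/")
    v <- rowMeans(rel)
    out <- setNames(rep(0, length(all_feats)), all_feats)
    out[names(v)] <- v
    out
  }, numeric(length(all_feats)))

  res <- list()
  for (t in thresholds) {
    detected <- mean_rel >= t
    first <- apply(detected, 1, function(row) {
      w <- which(row)
      if (length(w) == 0) NA_integer_ else w[1]
    })
    n_new <- vapply(seq_along(cycle_tables),
                    function(ci) sum(first == ci, na.rm = TRUE), numeric(1))
    res[[length(res) + 1L]] <- tibble(
      threshold = t,
      cycle_index = seq_along(cycle_tables) - 1L,
      cycle_label = labels, n_new = as.integer(n_new))
  }
  out <- bind_rows(res)
  class(out) <- c("emergence_curves", class(out))
  out
}
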