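#' Ternary coordinates of per-community mean abundances
#'
#' Places each function in ternary space by dividing its per-community mean
#' TPM by the triple's sum. Functions whose mean TPM across the three
#' communities is `<= min_mean_tpm` are excluded (the conventional
#' mean TPM > 0.5 inclusion rule).
#'
#' @param mean_tpm A tibble/data frame with an ID column and three
#'   per-community mean-TPM columns, or a numeric matrix (functions x 3).
#' @param communities Names of the three community columns (default
#'   `c("rhizcom", "sbrb", "soil")`).
#' @param min_mean_tpm Exclusion cutoff on the mean of the triple
#'   (default 0.5).
#' @return A tibble with the ID column, the three ternary proportions
#'   (columns `tern_<community>` summing to 1), `mean_tpm` and `included`.
#' @export
ternary_coords <- function(mean_tpm, communities = c("rhizcom", "sbrb", "soil"),
                           min_mean_tpm = 0.5) {
  if (is.matrix(mean_tpm)) {
    ids <- rownames(mean_tpm) %||% paste0("f", seq_len(nrow(mean_tpm)))
    m <- mean_tpm
    if (is.null(colnames(m))) colnames(m) <- communities
  } else {
    df <- as_tibble(mean_tpm)
    missing <- setdiff(communities, names(df))
    if (length(missing) > 0) {
      abort(paste0("Missing community column(s): ", paste(missing, collapse = ", ")))
    }
    id_col <- setdiff(names(df), communities)[1]
    ids <- as.character(df[[id_col]])
    m <- as.matrix(df[, communities])
  }
  if (any(m < 0)) abort("Mean TPM values must be non-negative.")
  row_mean <- rowMeans(m)
  included <- row_mean > min_mean_tpm
  tern <- matrix(NA_real_, nrow(m), 3,
                 dimnames = list(NULL, paste0("tern_", communities)))
  s <- rowSums(m)
  ok <- included & s > 0
  tern[ok, ] <- m[ok, ] / s[ok]
  out <- tibble(kegg_id = ids, mean_tpm = row_mean, included = included)
  bind_cols(out, as_tibble(tern))
}

#' Classify community dominance from three pairwise outcomes
#'
#' Given the outcomes of the three pairwise differential-abundance
#' comparisons between communities (for each ordered pair: which side was
#' significantly higher, or `ns`), assigns each function exactly one of
#' seven categories: a community is *enriched* when it is significantly
#' higher in both comparisons that involve it; *suppressed* when it is
#' significantly lower in both of its comparisons and no community is
#' enriched; everything else is *balanced*. With consistent pairwise
#' outcomes at most one community can be enriched and at most one
#' suppressed, so the classification is total and deterministic over all 27
#' outcome vectors.
#'
#' @param rhizcom_sbrb,rhizcom_soil,sbrb_soil Outcomes of the three pairs,
#'   each `"A_higher"`, `"B_higher"` or `"ns"` where A is the first-named
#'   community of the pair. Vectors are classified elementwise.
#' @return Character vector of categories (`enriched_rhizcom`, ...,
#'   `suppressed_soil`, `balanced`).
#' @export
dominance_classify <- function(rhizcom_sbrb, rhizcom_soil, sbrb_soil) {
  ok <- c("A_higher", "B_higher", "ns")
  n <- length(rhizcom_sbrb)
  if (length(rhizcom_soil) != n || length(sbrb_soil) != n) {
    abort("Outcome vectors must have equal length.")
  }
  for (v in list(rhizcom_sbrb, rhizcom_soil, sbrb_soil)) {
    if (!all(v %in% ok)) abort("Outcomes must be 'A_higher', 'B_higher' or 'ns'.")
  }
  higher <- cbind(
    rhizcom = (rhizcom_sbrb == "A_higher") & (rhizcom_soil == "A_higher"),
    sbrb = (rhizcom_sbrb == "B_higher") & (sbrb_soil == "A_higher"),
    soil = (rhizcom_soil == "B_higher") & (sbrb_soil == "B_higher"))
  lower <- cbind(
    rhizcom = (rhizcom_sbrb == "B_higher") & (rhizcom_soil == "B_higher"),
    sbrb = (rhizcom_sbrb == "A_higher") & (sbrb_soil == "B_higher"),
    soil = (rhizcom_soil == "A_higher") & (sbrb_soil == "A_higher"))
  out <- rep("balanced", n)
  for (cm in colnames(higher)) out[higher[, cm]] <- paste0("enriched_", cm)
  none_enriched <- rowSums(higher) == 0
  for (cm in colnames(lower)) {
    out[none_enriched & lower[, cm]] <- paste0("suppressed_", cm)
  }
  out
}

#' Dominance records from three pairwise DA results
#'
#' Joins the three pairwise [nb_wald()] results on feature ID, derives each
#' pair's outcome from the significance rule (significant and log2fc > 0
#' means the numerator community is higher), classifies dominance, and
#' attaches ternary coordinates from a per-community mean-TPM table.
#'
#' @param da_rhizcom_sbrb,da_rhizcom_soil,da_sbrb_soil [nb_wald()] results
#'   whose numerator (`group_a`) is the first-named community.
#' @param mean_tpm Per-function mean TPM tibble or matrix (see
#'   [ternary_coords()]).
#' @param min_mean_tpm Inclusion cutoff (default 0.5).
#' @return A tibble of class `dominance_records`: `kegg_id`, outcome
#'   columns, `category`, ternary coordinates, `mean_tpm`, `included`.
#' @export
dominance_records <- function(da_rhizcom_sbrb, da_rhizcom_soil, da_sbrb_soil,
                              mean_tpm, min_mean_tpm = 0.5) {
  outcome <- function(da) {
    o <- rep("ns", nrow(da))
    o[da$significant & da$log2fc > 0] <- "A_higher"
    o[da$significant & da$log2fc < 0] <- "B_higher"
    setNames(o, da$feature_id)
  }
  o1 <- outcome(da_rhizcom_sbrb)
  o2 <- outcome(da_rhizcom_soil)
  o3 <- outcome(da_sbrb_soil)
  ids <- Reduce(intersect, list(names(o1), names(o2), names(o3)))
  if (length(ids) == 0) abort("No features shared by the three DA results.")
  tern <- ternary_coords(mean_tpm, min_mean_tpm = min_mean_tpm)
  out <- tibble(kegg_id = ids,
                rhizcom_sbrb = unname(o1[ids]),
                rhizcom_soil = unname(o2[ids]),
                sbrb_soil = unname(o3[ids]),
                category = dominance_classify(o1[ids], o2[ids], o3[ids]))
  out <- left_join(out, tern, by = "kegg_id")
  class(out) <- c("dominance_records", class(out))
  out
}

#' Per-hierarchy dominance-category fractions
#'
#' Rolls dominance categories up to broad functional hierarchies (e.g. KEGG
#' BRITE classes) and reports the fraction of each hierarchy's functions in
#' every category. Functions without a hierarchy mapping fall into an
#' `unmapped` bucket.
#'
#' @param records A [dominance_records()] tibble (needs `kegg_id`,
#'   `category`).
#' @param brite_map Tibble/data frame with `kegg_id` and `hierarchy`.
#' @return A tibble `hierarchy`, `category`, `n`, `fraction` (fractions sum
#'   to 1 within each hierarchy).
#' @export
hierarchy_fractions <- function(records, brite_map) {
  brite_map <- as_tibble(brite_map)
  if (!all(c("kegg_id", "hierarchy") %in% names(brite_map))) {
    abort("`brite_map` needs `kegg_id` and `hierarchy` columns.")
  }
  df <- left_join(as_tibble(records)[, c("kegg_id", "category")],
                  brite_map, by = "kegg_id")
  df$hierarchy[is.na(df$hierarchy)] <- "unmapped"
  df |>
    count(.data$hierarchy, .data$category, name = "n") |>
    group_by(.data$hierarchy) |>
    mutate(fraction = .data$n / sum(.data$n)) |>
    ungroup()
}
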