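#' MAG quality tier from completeness and contamination
#'
#' Standard-metric tiers: discarded when contamination >= 10%; otherwise
#' high (> 90% completeness, < 5% contamination), good (> 75%, < 10%),
#' medium (> 50%, < 10%), low (<= 50%, < 10%). Contamination dominates;
#' inequalities are strict where printed.
#'
#' @param completeness,contamination Percentages (vectorized).
#' @return Character vector in
#'   `c("high", "good", "medium", "low", "discarded")`.
#' @examples
#' quality_category(95, 2)   # "high"
#' quality_category(95, 12)  # "discarded"
#' @export
quality_category <- function(completeness, contamination) {
  if (any(completeness < 0 | completeness > 100)) {
    abort("`completeness` must be in [0, 100].")
  }
  if (any(contamination < 0)) abort("`contamination` must be >= 0.")
  dplyr::case_when(
    contamination >= 10 ~ "discarded",
    completeness > 90 & contamination < 5 ~ "high",
    completeness > 75 ~ "good",
    completeness > 50 ~ "medium",
    TRUE ~ "low")
}

#' Assign a MAG to its community by the 1.5x TPM rule
#'
#' A MAG is assigned to a single community when its mean TPM percentage
#' there is at least `ratio` times that of each other community; otherwise
#' it is assigned to every community whose TPM percentage is within a
#' factor `ratio` of the maximum (zero values are excluded). A value
#' exactly at the boundary satisfies the `>=` of the single-community
#' clause, so boundary ties fall to the singleton branch only when the
#' maximum dominates both others.
#'
#' @param tpm Numeric length-3 vector (or matrix with 3 columns) of mean
#'   TPM percentages, named or ordered as `communities`.
#' @param communities Community names (default rhizcom, sbrb, soil).
#' @param ratio Dominance ratio (default 1.5).
#' @return For a vector input, a character vector (the non-empty assigned
#'   set); for a matrix, a list of such vectors.
#' @examples
#' assign_community(c(60, 10, 10))  # "rhizcom"
#' assign_community(c(30, 25, 5))   # c("rhizcom", "sbrb")
#' @export
assign_community <- function(tpm, communities = c("rhizcom", "sbrb", "soil"),
                             ratio = 1.5) {
  if (is.matrix(tpm)) {
    return(lapply(seq_len(nrow(tpm)), function(i) {
      assign_community(tpm[i, ], communities, ratio)
    }))
  }
  if (length(tpm) != length(communities)) {
    abort("`tpm` must have one value per community.")
  }
  if (any(tpm < 0)) abort("TPM values must be non-negative.")
  if (all(tpm == 0)) abort("All-zero TPM triple cannot be assigned.")
  names(tpm) <- communities
  mx <- max(tpm)
  winner <- communities[which.max(tpm)]
  others <- tpm[setdiff(communities, winner)]
  if (all(mx >= ratio * others)) {
    winner
  } else {
    communities[tpm > 0 & mx / tpm < ratio]
  }
}

#' Reaction-set pathway completeness
#'
#' A rule lists alternative routes, each a set of KEGG reaction IDs that
#' must all be present. The pathway is complete when some route is a subset
#' of the MAG's reactions; `best_route_fraction` is the best per-route
#' coverage.
#'
#' @param reactions Character vector of KEGG reaction IDs present in the
#'   MAG.
#' @param rule A rule (list with `name` and `routes`), e.g. one element of
#'   [default_reaction_rules()].
#' @return A list `complete` (flag) and `best_route_fraction`.
#' @examples
#' rules <- default_reaction_rules()
#' pathway_complete(c("R07407"), rules$nicotinate)$complete  # TRUE
#' @export
pathway_complete <- function(reactions, rule) {
  if (is.null(rule$routes) || length(rule$routes) == 0) {
    abort("Rule must contain at least one route.")
  }
  if (any(lengths(rule$routes) == 0)) abort("Routes must be non-empty.")
  frac <- vapply(rule$routes, function(route) {
    length(intersect(route, reactions)) / length(route)
  }, numeric(1))
  list(complete = any(frac == 1), best_route_fraction = max(frac))
}

#' Pathway completeness across a MAG table
#'
#' @param mags MAG tibble with `mag_id` and a `reactions` list-column.
#' @param rules Named list of rules (default [default_reaction_rules()]).
#' @return A tibble `mag_id`, `rule`, `complete`, `best_route_fraction`.
#' @export
pathway_completeness_table <- function(mags, rules = default_reaction_rules()) {
  rows <- list()
  for (rn in names(rules)) {
    res <- map(mags$reactions, pathway_complete, rule = rules[[rn]])
    rows[[rn]] <- tibble(mag_id = mags$mag_id, rule = rn,
                         complete = map_lgl(res, "complete"),
                         best_route_fraction = map_dbl(res, "best_route_fraction"))
  }
  bind_rows(rows)
}

#' Annotate a MAG table with quality tiers and community assignments
#'
#' @param mags MAG tibble (columns `mag_id`, `completeness`,
#'   `contamination`, `tpm_rhizcom`, `tpm_sbrb`, `tpm_soil`).
#' @param ratio Dominance ratio for [assign_community()].
#' @return The tibble with added `quality` and `assigned` (list-column of
#'   community sets) and `assigned_label` (communities joined by `+`).
#' @export
annotate_mags <- function(mags, ratio = 1.5) {
  tpm <- as.matrix(mags[, c("tpm_rhizcom", "tpm_sbrb", "tpm_soil")])
  assigned <- assign_community(tpm, ratio = ratio)
  mags |>
    mutate(quality = quality_category(.data$completeness, .data$contamination),
           assigned = assigned,
           assigned_label = map_chr(assigned, paste, collapse = "+"))
}

#' Compare per-category annotation counts across assigned communities
#'
#' Kruskal-Wallis test of a per-MAG annotation count (e.g. the number of
#' annotations in a KEGG pathway category) grouped by assigned community.
#' Multi-assigned MAGs are counted once per assigned community by default
#' (`count_multi = "all"`) or only in their top community
#' (`count_multi = "first"`). When all values are identical across MAGs the
#' p value is NaN (not computed due to insufficient variability).
#'
#' @param mags An [annotate_mags()] result (needs `assigned`).
#' @param category Name of the numeric per-MAG count column.
#' @param count_multi `"all"` or `"first"`.
#' @return A list of class `category_comparison`: `$p`, `$statistic`,
#'   `$df`, `$medians` (tibble `community`, `n`, `median`), `$category`.
#' @export
category_comparison <- function(mags, category, count_multi = c("all", "first")) {
  count_multi <- match.arg(count_multi)
  if (!category %in% names(mags)) {
    abort(paste0("Category column not found: ", category))
  }
  if (!"assigned" %in% names(mags)) abort("Run annotate_mags() first.")
  sets <- if (count_multi == "first") map(mags$assigned, 1) else mags$assigned
  values <- rep(mags[[category]], lengths(sets))
  groups <- unlist(sets)
  if (all(is.na(values)) || length(values) == 0) {
    abort(paste0("Category has no values: ", category))
  }
  tab <- table(groups)
  if (length(tab) < 2 || any(tab < 2)) {
    abort("Need >= 2 communities with >= 2 MAGs each.")
  }
  medians <- tibble(community = names(tab), n = as.integer(tab),
                    median = vapply(names(tab), function(g) {
                      median(values[groups == g])
                    }, numeric(1), USE.NAMES = FALSE))
  if (length(unique(values)) == 1) {
    res <- list(p = NaN, statistic = NaN, df = length(tab) - 1L,
                medians = medians, category = category)
  } else {
    kw <- kruskal.test(values, factor(groups))
    res <- list(p = kw$p.value, statistic = unname(kw$statistic),
                df = unname(kw$parameter), medians = medians,
                category = category)
  }
  structure(res, class = "category_comparison")
}

#' @export
print.category_comparison <- function(x, ...) {
  cat(sprintf("<category_comparison> %s: KW chi2 = %.3g (df %d), p = %.3g\n",
              x$category, x$statistic, x$df, x$p))
  print(x$medians)
  invisible(x)
}

#' Tidy a category comparison
#' @param x A `category_comparison`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.category_comparison <- function(x, ...) {
  mutate(x$medians, category = x$category, p = x$p, statistic = x$statistic)
}
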