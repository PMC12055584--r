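#' Kruskal-Wallis test with rank-based Fisher LSD letters
#'
#' Kruskal-Wallis on mid-ranks (tie-corrected), followed by Fisher's least
#' significant difference criterion applied to rank sums: pairwise t
#' statistics on mean ranks with the pooled rank variance
#' `S2 * (N - 1 - H) / (N - k)`, BH-adjusted pairwise p values, and a
#' compact letter display in which groups sharing a letter are not
#' significantly different at `alpha`.
#'
#' @param values Numeric vector.
#' @param groups Group labels, >= 2 groups with >= 2 observations each.
#' @param alpha Significance level for the letters (default 0.01).
#' @return A list of class `kw_lsd`: `$kw` (tibble `statistic`, `df`, `p`),
#'   `$pairwise` (tibble `group1`, `group2`, `diff_rank`, `p`, `padj`),
#'   `$letters` (tibble `group`, `n`, `mean_rank`, `letter`).
#' @export
kruskal_wallis_lsd <- function(values, groups, alpha = 0.01) {
  groups <- as.character(groups)
  if (length(values) != length(groups)) abort("Input lengths differ.")
  tab <- table(groups)
  if (length(tab) < 2) abort("Need >= 2 groups.")
  if (any(tab < 2)) {
    abort(paste0("Group(s) with < 2 observations: ",
                 paste(names(tab)[tab < 2], collapse = ", ")))
  }
  kw <- kruskal.test(values, factor(groups))
  r <- rank(values)
  N <- length(values)
  k <- length(tab)
  # tie-corrected variance of the ranks
  S2 <- (sum(r^2) - N * (N + 1)^2 / 4) / (N - 1)
  H <- unname(kw$statistic)
  mse <- S2 * (N - 1 - H) / (N - k)
  mean_rank <- vapply(names(tab), function(g) mean(r[groups == g]), numeric(1))

  pairs <- utils::combn(names(tab), 2)
  pw <- map(seq_len(ncol(pairs)), function(i) {
    g1 <- pairs[1, i]; g2 <- pairs[2, i]
    se <- sqrt(mse * (1 / tab[[g1]] + 1 / tab[[g2]]))
    tstat <- (mean_rank[[g1]] - mean_rank[[g2]]) / se
    tibble(group1 = g1, group2 = g2,
           diff_rank = mean_rank[[g1]] - mean_rank[[g2]],
           p = 2 * pt(-abs(tstat), N - k))
  }) |> bind_rows()
  pw$padj <- bh_adjust(pw$p)

  letters <- compact_letters(names(tab), pw, alpha)
  structure(list(kw = tibble(statistic = H, df = unname(kw$parameter),
                             p = kw$p.value),
                 pairwise = pw,
                 letters = tibble(group = names(tab), n = as.integer(tab),
                                  mean_rank = unname(mean_rank),
                                  letter = unname(letters[names(tab)]))),
            class = "kw_lsd")
}

# drop sets fully contained in a larger set, and exact duplicates
absorb_sets <- function(sets) {
  sets <- unique(lapply(sets, sort))
  keep <- rep(TRUE, length(sets))
  for (a in seq_along(sets)) {
    for (b in seq_along(sets)) {
      if (a != b && keep[b] && length(sets[[a]]) < length(sets[[b]]) &&
          all(sets[[a]] %in% sets[[b]])) {
        keep[a] <- FALSE
      }
    }
  }
  sets[keep]
}

# Insert-and-absorb compact letter display. `pw` needs group1/group2/padj.
# Groups in the same letter set are NOT significantly different.
compact_letters <- function(group_names, pw, alpha) {
  sig <- pw[!is.na(pw$padj) & pw$padj <= alpha, , drop = FALSE]
  sets <- list(group_names)
  for (i in seq_len(nrow(sig))) {
    g1 <- sig$group1[i]; g2 <- sig$group2[i]
    new_sets <- list()
    for (s in sets) {
      if (g1 %in% s && g2 %in% s) {
        new_sets <- c(new_sets, list(setdiff(s, g1)), list(setdiff(s, g2)))
      } else {
        new_sets <- c(new_sets, list(s))
      }
    }
    sets <- absorb_sets(new_sets)
  }
  sets <- sets[lengths(sets) > 0]
  sets <- sets[order(vapply(sets, function(s) min(match(s, group_names)), numeric(1)))]
  out <- setNames(rep("", length(group_names)), group_names)
  for (i in seq_along(sets)) {
    lab <- letters[i]
    for (g in sets[[i]]) out[g] <- paste0(out[g], lab)
  }
  out
}

#' @export
print.kw_lsd <- function(x, ...) {
  cat(sprintf("<kw_lsd> KW chi2 = %.4g (df %d), p = %.3g\n",
              x$kw$statistic, x$kw$df, x$kw$p))
  print(x$letters)
  invisible(x)
}

#' Tidy Kruskal-Wallis + LSD letters
#' @param x A `kw_lsd` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.kw_lsd <- function(x, ...) x$letters

#' One-row summary of a `kw_lsd` fit
#' @param x A `kw_lsd` object.
#' @param ... Unused.
#' @exportS3Method generics::glance
glance.kw_lsd <- function(x, ...) x$kw

#' Wilcoxon rank-sum test
#'
#' Exact p for `min(n_x, n_y) <= 8` without ties; normal approximation with
#' tie correction otherwise. The method used is reported.
#'
#' @param x,y Numeric samples (non-empty).
#' @param alternative `"two_sided"` or `"greater"` (x tends greater).
#' @return A tibble `statistic`, `p`, `method`, `alternative`.
#' @examples
#' wilcoxon_rank_sum(c(4, 5, 6), c(1, 2, 3), "greater")$p  # 0.05
#' @export
wilcoxon_rank_sum <- function(x, y, alternative = c("two_sided", "greater")) {
  alternative <- match.arg(alternative)
  if (length(x) == 0 || length(y) == 0) abort("Samples must be non-empty.")
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- min(length(x), length(y)) <= 8 && !ties
  wt <- suppressWarnings(
    wilcox.test(x, y, alternative = sub("_", ".", alternative),
                exact = exact, correct = !exact))
  tibble(statistic = unname(wt$statistic), p = wt$p.value,
         method = if (exact) "exact" else "normal_approximation",
         alternative = alternative)
}

#' Analysis of similarity (ANOSIM)
#'
#' Rank-based contrast of between- versus within-group dissimilarities,
#' `R = (mean_between - mean_within) / (M / 2)` with `M = n(n-1)/2`, with a
#' one-sided permutation p value `(count >= observed + 1) / (n_perm + 1)`.
#' Delegates to [vegan::anosim()] (the conventional implementation) with a
#' seedable permutation stream.
#'
#' @param d Distance matrix (or `dist`).
#' @param groups Group labels (>= 2 groups, >= 2 members each).
#' @param n_perm Number of permutations (default 9999).
#' @param seed Optional integer seed for the permutation stream.
#' @return A tibble `R`, `p`, `n_perm`.
#' @export
anosim_test <- function(d, groups, n_perm = 9999, seed = NULL) {
  groups <- as.character(groups)
  tab <- table(groups)
  if (length(tab) < 2) abort("Need >= 2 groups.")
  if (any(tab < 2)) abort("Each group needs >= 2 members.")
  run <- function() vegan::anosim(as.dist(as.matrix(d)), grouping = factor(groups),
                                  permutations = n_perm)
  fit <- if (is.null(seed)) run() else withr_seed(seed, run)
  tibble(R = fit$statistic, p = fit$signif, n_perm = n_perm)
}

#' Permutational multivariate analysis of variance (PERMANOVA)
#'
#' Partition of squared dissimilarities with a pseudo-F statistic and a
#' permutation p value, via [vegan::adonis2()].
#'
#' @inheritParams anosim_test
#' @return A tibble `pseudo_F`, `R2`, `p`, `n_perm`.
#' @export
permanova_test <- function(d, groups, n_perm = 9999, seed = NULL) {
  groups <- as.character(groups)
  tab <- table(groups)
  if (length(tab) < 2) abort("Need >= 2 groups.")
  if (any(tab < 2)) abort("Each group needs >= 2 members.")
  df <- data.frame(group = factor(groups))
  dd <- as.dist(as.matrix(d))
  run <- function() vegan::adonis2(dd ~ group, data = df, permutations = n_perm)
  fit <- if (is.null(seed)) run() else withr_seed(seed, run)
  tibble(pseudo_F = fit$F[1], R2 = fit$R2[1], p = fit$`Pr(>F)`[1],
         n_perm = n_perm)
}

# run fn under a temporary RNG seed, restoring the caller's stream
withr_seed <- function(seed, fn) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  fn()
}

#' Control-subtracted growth normalization
#'
#' Subtracts, within each strain set, the mean c.f.u. of the no-carbon
#' (`none`) control replicates from every measurement. Negative normalized
#' values are retained and flagged.
#'
#' @param records Growth tibble (`strains`, `focal_strain`, `carbon_source`,
#'   `replicate`, `cfu`).
#' @return The tibble with added `cfu_normalized` and `below_control`.
#' @export
normalize_growth <- function(records) {
  records <- as_tibble(records)
  controls <- records |>
    filter(.data$carbon_source == "none") |>
    group_by(.data$strains) |>
    summarise(control_mean = mean(.data$cfu), .groups = "drop")
  missing <- setdiff(unique(records$strains), controls$strains)
  if (length(missing) > 0) {
    abort(paste0("No 'none' control for strain set(s): ",
                 paste(missing, collapse = ", ")))
  }
  records |>
    left_join(controls, by = "strains") |>
    mutate(cfu_normalized = .data$cfu - .data$control_mean,
           below_control = .data$cfu_normalized < 0) |>
    select(-"control_mean")
}

#' Facilitation test for co-culture growth
#'
#' One-sided Wilcoxon rank-sum test of the hypothesis that a partner
#' strain's normalized growth in co-culture with a helper exceeds its
#' monoculture growth (`greater` alternative).
#'
#' @param partner_cocult,partner_monocult Normalized c.f.u. vectors
#'   (>= 3 replicates each).
#' @return A tibble as from [wilcoxon_rank_sum()].
#' @export
facilitation_test <- function(partner_cocult, partner_monocult) {
  if (length(partner_cocult) < 3 || length(partner_monocult) < 3) {
    abort("Need >= 3 replicates per condition.")
  }
  wilcoxon_rank_sum(partner_cocult, partner_monocult, alternative = "greater")
}
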