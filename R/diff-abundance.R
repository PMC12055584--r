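#' Median-of-ratios size factors
#'
#' The standard companion normalization of the negative-binomial Wald test:
#' each sample's factor is the median, over features, of the ratio between
#' the sample's count and the feature's geometric mean across samples.
#' Features with a zero in any sample are excluded from the reference; when
#' no feature is positive in every sample, geometric means are computed over
#' positive counts only (logged fallback). Factors are normalized to
#' geometric mean 1.
#'
#' @param x A [rhizo_counts] or count matrix.
#' @return Named positive numeric vector of per-sample factors.
#' @export
size_factors <- function(x) {
  m <- count_matrix(x)
  all_pos <- rowSums(m == 0) == 0
  if (any(all_pos)) {
    geo <- exp(rowMeans(log(m[all_pos, , drop = FALSE])))
    f <- apply(sweep(m[all_pos, , drop = FALSE], 1, geo, "/"), 2, median)
  } else {
    inform("No feature is nonzero in all samples; using positive-count geometric means.")
    lm0 <- log(m)
    lm0[!is.finite(lm0)] <- NA
    geo <- exp(rowMeans(lm0, na.rm = TRUE))
    keep <- is.finite(geo) & rowSums(m > 0) > 0
    f <- vapply(seq_len(ncol(m)), function(j) {
      median(m[keep, j] / geo[keep], na.rm = TRUE)
    }, numeric(1))
  }
  f <- f / exp(mean(log(f)))
  setNames(f, colnames(m))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up BH with monotonicity enforcement. Missing p values are excluded
#' from the ranking (they do not inflate the number of tests) and propagated
#' as NA.
#'
#' @param p Numeric vector of p values in `[0, 1]` (NA/NaN allowed).
#' @return Adjusted p values, same length and order.
#' @export
bh_adjust <- function(p) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) abort("p values must lie in [0, 1].")
  out <- rep(NA_real_, length(p))
  out[ok] <- p.adjust(p[ok], method = "BH")
  out
}

#' Negative-binomial Wald differential abundance test
#'
#' A self-contained NB Wald test for two-group feature count tables, in the
#' style the field's standard tool applies to ASV and KEGG tables: counts
#' are normalized by median-of-ratios size factors; per-feature dispersions
#' are estimated by method of moments, then shrunk on the log scale toward a
#' mean-dispersion trend `a / mu + b` fitted across features; group means
#' are the means of normalized counts (the NB maximum-likelihood solution
#' when factors are equal within a group, and exactly invariant to
#' rescaling a sample's counts), with Wald standard errors from the Fisher
#' information of the log mean at the fixed dispersion; the Wald statistic
#' `log2fc / se` is referred to the normal
#' distribution, p values are BH-adjusted, and a feature is flagged
#' significant when `|log2fc| >= lfc_min` and `padj < alpha`.
#'
#' Deliberate simplifications relative to the reference tool: no
#' Cook's-distance outlier handling, no independent filtering, no LFC
#' shrinkage.
#'
#' @param x A [rhizo_counts] or count matrix.
#' @param groups Factor/character vector over samples with exactly two
#'   levels, each with >= 2 samples.
#' @param group_a,group_b Numerator and denominator group labels (defaults:
#'   first and second level).
#' @param lfc_min Minimum absolute log2 fold change for significance
#'   (default 2.5).
#' @param alpha Adjusted-p cutoff (default 0.01).
#' @param shrink_weight Weight of the trend in the log-scale dispersion
#'   shrinkage (0 = raw method of moments, 1 = pure trend; default 0.85).
#' @param min_total Features with total count across samples below this are
#'   excluded before testing (default 0; metagenome-function analyses
#'   conventionally use 1000).
#' @return A tibble of class `nb_wald` with columns `feature_id`,
#'   `base_mean`, `log2fc`, `se`, `wald_stat`, `p`, `padj`, `significant`;
#'   attributes `groups`, `size_factors`, `dispersions`, `excluded`.
#' @export
nb_wald <- function(x, groups, group_a = NULL, group_b = NULL,
                    lfc_min = 2.5, alpha = 0.01, shrink_weight = 0.85,
                    min_total = 0) {
  m <- count_matrix(x)
  groups <- as.character(groups)
  if (length(groups) != ncol(m)) abort("`groups` must have one label per sample.")
  levs <- unique(groups)
  if (length(levs) != 2) abort("Exactly two groups are required.")
  group_a <- group_a %||% levs[1]
  group_b <- group_b %||% levs[2]
  if (!all(c(group_a, group_b) %in% levs)) abort("Unknown group label.")
  if (any(table(groups) < 2)) abort("Each group needs >= 2 samples.")

  excluded <- tibble(feature_id = character(), reason = character())
  low <- rowSums(m) < min_total
  if (any(low)) {
    excluded <- bind_rows(excluded, tibble(feature_id = rownames(m)[low],
                                           reason = "below_min_total"))
    m <- m[!low, , drop = FALSE]
  }
  allzero <- rowSums(m) == 0
  if (any(allzero)) {
    excluded <- bind_rows(excluded, tibble(feature_id = rownames(m)[allzero],
                                           reason = "all_zero"))
    m <- m[!allzero, , drop = FALSE]
  }
  if (nrow(m) == 0) abort("No testable features remain.")

  sf <- size_factors(m)
  z <- sweep(m, 2, sf, "/")
  ja <- which(groups == group_a)
  jb <- which(groups == group_b)

  disp <- estimate_dispersions(m, z, sf, list(ja, jb), shrink_weight)

  fit_a <- nb_fit_group(m[, ja, drop = FALSE], sf[ja], disp$final)
  fit_b <- nb_fit_group(m[, jb, drop = FALSE], sf[jb], disp$final)
  log2fc <- unname(fit_a$log_mu - fit_b$log_mu) / log(2)
  se <- unname(sqrt(1 / fit_a$info + 1 / fit_b$info)) / log(2)
  wald <- log2fc / se
  p <- 2 * pnorm(-abs(wald))
  padj <- bh_adjust(p)
  res <- tibble(feature_id = rownames(m),
                base_mean = rowMeans(z),
                log2fc = log2fc, se = se, wald_stat = wald,
                p = p, padj = padj,
                significant = !is.na(padj) & abs(log2fc) >= lfc_min & padj < alpha)
  attr(res, "groups") <- c(group_a = group_a, group_b = group_b)
  attr(res, "size_factors") <- sf
  attr(res, "dispersions") <- disp
  attr(res, "excluded") <- excluded
  attr(res, "lfc_min") <- lfc_min
  attr(res, "alpha") <- alpha
  class(res) <- c("nb_wald", class(res))
  res
}

# Method-of-moments dispersions with log-scale shrinkage toward a fitted
# a/mu + b trend. Features whose moment estimate collapses to the floor
# (sub-Poisson variance) take the trend value.
estimate_dispersions <- function(m, z, sf, group_idx, shrink_weight,
                                 floor = 1e-8) {
  mu_all <- rowMeans(z)
  per_group <- lapply(group_idx, function(j) {
    zg <- z[, j, drop = FALSE]
    mu <- rowMeans(zg)
    v <- apply(zg, 1, var)
    shot <- mu * mean(1 / sf[j])  # Poisson component on the common scale
    (v - shot) / mu^2
  })
  raw <- Reduce(`+`, per_group) / length(per_group)
  raw[!is.finite(raw)] <- NA
  mom <- pmax(raw, floor)

  usable <- !is.na(raw) & raw > floor & mu_all > 0
  if (sum(usable) >= 10) {
    fit <- stats::lm.fit(cbind(1 / mu_all[usable], 1), raw[usable])
    a <- max(fit$coefficients[1], 0)
    b <- max(fit$coefficients[2], floor)
  } else {
    a <- 0
    b <- max(median(raw[usable], na.rm = TRUE), floor)
    if (!is.finite(b)) b <- 0.1
  }
  trend <- pmax(a / pmax(mu_all, 1e-8) + b, floor)
  final <- exp((1 - shrink_weight) * log(mom) + shrink_weight * log(trend))
  final[is.na(raw)] <- trend[is.na(raw)]
  list(mom = mom, trend = trend, final = final, coef = c(a = a, b = b))
}

# Per-group NB mean fit with fixed dispersion: the mean of size-factor
# normalized counts, which solves the NB score equation exactly when the
# factors within the group are equal and makes log fold changes exactly
# invariant to rescaling a sample's counts. The Wald SE comes from the
# observed Fisher information of log(mu) at the fitted mean. Groups with
# all-zero counts are floored at half a count over the group's total size
# factor.
nb_fit_group <- function(counts, sf, alpha) {
  z <- sweep(counts, 2, sf, "/")
  mu <- pmax(rowMeans(z), 0.5 / sum(sf))
  smu <- outer(mu, sf)               # features x samples expected counts
  info <- rowSums(smu / (1 + sweep(smu, 1, alpha, "*")))
  list(log_mu = log(mu), info = pmax(info, 1e-12))
}

#' @export
print.nb_wald <- function(x, ...) {
  g <- attr(x, "groups")
  cat(sprintf("<nb_wald> %s vs %s: %d features tested, %d significant (|log2FC| >= %.2g, padj < %.2g)\n",
              g[["group_a"]], g[["group_b"]], nrow(x), sum(x$significant),
              attr(x, "lfc_min"), attr(x, "alpha")))
  NextMethod()
}

#' Tidy an NB Wald result
#' @param x An `nb_wald` result.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.nb_wald <- function(x, ...) as_tibble(x)

#' One-row summary of an NB Wald result
#' @param x An `nb_wald` result.
#' @param ... Unused.
#' @exportS3Method generics::glance
glance.nb_wald <- function(x, ...) {
  g <- attr(x, "groups")
  tibble(group_a = g[["group_a"]], group_b = g[["group_b"]],
         n_tested = nrow(x), n_significant = sum(x$significant),
         n_up = sum(x$significant & x$log2fc > 0),
         n_down = sum(x$significant & x$log2fc < 0),
         n_excluded = nrow(attr(x, "excluded")),
         lfc_min = attr(x, "lfc_min"), alpha = attr(x, "alpha"))
}
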