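#' Cumulative sum scaling (CSS) normalization
#'
#' Per-sample scaling robust to a few dominant features: each sample's
#' factor is the sum of its counts that are less than or equal to the
#' sample's empirical quantile (over its nonzero counts) at `quantile`;
#' counts are divided by the factor and multiplied by `scale_constant`.
#' With `quantile = "auto"` the quantile is chosen by the published CSS
#' heuristic: the smallest quantile at which the relative instability of the
#' median cumulative sum between successive grid quantiles exceeds 0.1.
#'
#' Within-sample ratios of nonzero features are preserved exactly.
#'
#' @param x A [rhizo_counts] or a non-negative count matrix (features x
#'   samples).
#' @param quantile A proportion in (0, 1), or `"auto"`.
#' @param scale_constant Constant the scaled counts are multiplied by
#'   (default 1000).
#' @return A list of class `css_norm`: `$normalized` (numeric matrix),
#'   `$scaling` (tibble `sample_id`, `factor`), `$quantile_used`,
#'   `$scale_constant`.
#' @export
css_normalize <- function(x, quantile = "auto", scale_constant = 1000) {
  m <- count_matrix(x)
  zero <- colSums(m) == 0
  if (any(zero)) {
    abort(paste0("All-zero sample(s): ",
                 paste(colnames(m)[zero], collapse = ", ")))
  }
  if (identical(quantile, "auto")) quantile <- css_auto_quantile(m)
  if (!is.numeric(quantile) || quantile <= 0 || quantile >= 1) {
    abort("`quantile` must lie in (0, 1) or be \"auto\".")
  }
  factors <- css_factors(m, quantile)
  normalized <- sweep(m, 2, factors, "/") * scale_constant
  structure(list(normalized = normalized,
                 scaling = tibble(sample_id = colnames(m), factor = factors),
                 quantile_used = quantile, scale_constant = scale_constant),
            class = "css_norm")
}

# factor_j = sum of counts <= the sample's empirical quantile of its
# nonzero counts (type-7 quantile).
css_factors <- function(m, p) {
  vapply(seq_len(ncol(m)), function(j) {
    cj <- m[, j]
    q <- stats::quantile(cj[cj > 0], p, type = 7, names = FALSE)
    sum(cj[cj <= q])
  }, numeric(1))
}

# Published CSS heuristic at desk scale: per-sample quantile profiles of the
# nonzero counts are compared to their median reference profile; the chosen
# quantile is the smallest at which the relative instability of the median
# deviation between successive quantiles exceeds `threshold`. As in the
# published procedure, choices below the 0.5 quantile fall back to 0.5.
css_auto_quantile <- function(m, threshold = 0.1) {
  qs <- seq(0.01, 0.99, by = 0.01)
  prof <- vapply(seq_len(ncol(m)), function(j) {
    cj <- m[, j]
    stats::quantile(cj[cj > 0], qs, type = 7, names = FALSE)
  }, numeric(length(qs)))
  ref <- apply(prof, 1, median)
  devi <- apply(abs(prof - ref), 1, median)
  rel <- abs(diff(devi)) / pmax(devi[-1], .Machine$double.eps)
  hit <- which(rel > threshold)[1]
  x <- if (is.na(hit)) 0.5 else qs[hit + 1]
  if (x < 0.5) {
    inform("CSS instability below the 0.5 quantile; using the default 0.5.")
    x <- 0.5
  }
  x
}

#' @export
print.css_norm <- function(x, ...) {
  cat(sprintf("<css_norm> %d samples, quantile %.2f, factors %.0f-%.0f\n",
              nrow(x$scaling), x$quantile_used,
              min(x$scaling$factor), max(x$scaling$factor)))
  invisible(x)
}

#' Tidy CSS scaling factors
#' @param x A `css_norm` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.css_norm <- function(x, ...) x$scaling

#' Shannon diversity
#'
#' `-sum(p_i * log(p_i))` over nonzero proportions, in natural log by
#' default.
#'
#' @param counts Non-negative abundance vector with positive sum.
#' @param base Logarithm base (default `exp(1)`, i.e. nats).
#' @return Shannon index H.
#' @examples
#' shannon(rep(1, 10)) # log(10)
#' @export
shannon <- function(counts, base = exp(1)) {
  if (any(counts < 0)) abort("`counts` must be non-negative.")
  s <- sum(counts)
  if (s <= 0) abort("`counts` must have a positive sum.")
  p <- counts[counts > 0] / s
  -sum(p * log(p, base = base))
}

#' Observed features (richness)
#'
#' @param counts Non-negative abundance vector.
#' @return Number of features with count > 0.
#' @export
observed_features <- function(counts) sum(counts > 0)

#' Faith's phylogenetic diversity
#'
#' Sum of branch lengths of the minimal subtree spanning the present tips,
#' including the path to the root by default (the conventional rooted PD).
#'
#' @param present_tips Character vector of tip labels present in the sample.
#' @param tree A rooted [ape::phylo] with branch lengths.
#' @param include_root Include the edges from the tip set's most recent
#'   common ancestor up to the root (default TRUE).
#' @return Branch-length sum.
#' @examples
#' tr <- ape::read.tree(text = "((A:1,B:1):1,C:3):0;")
#' faith_pd(c("A", "B"), tr) # 3
#' @export
faith_pd <- function(present_tips, tree, include_root = TRUE) {
  if (is.null(tree$edge.length)) abort("Tree has no branch lengths.")
  unknown <- setdiff(present_tips, tree$tip.label)
  if (length(unknown) > 0) {
    abort(paste0("Tips not in tree: ", paste(unknown, collapse = ", ")))
  }
  if (length(present_tips) == 0) return(0)
  n_tip <- length(tree$tip.label)
  root <- n_tip + 1L
  parent_edge <- integer(max(tree$edge))  # edge index leading into each node
  parent_edge[tree$edge[, 2]] <- seq_len(nrow(tree$edge))
  parent_node <- integer(max(tree$edge))
  parent_node[tree$edge[, 2]] <- tree$edge[, 1]

  tip_idx <- match(present_tips, tree$tip.label)
  on_path <- logical(nrow(tree$edge))
  for (node in tip_idx) {
    while (node != root) {
      e <- parent_edge[node]
      if (on_path[e]) break  # remainder of the path already marked
      on_path[e] <- TRUE
      node <- parent_node[node]
    }
  }
  if (!include_root && length(tip_idx) >= 2) {
    mrca <- ape::getMRCA(tree, tip_idx)
    # drop edges on the path from the MRCA up to the root
    node <- mrca
    while (node != root) {
      on_path[parent_edge[node]] <- FALSE
      node <- parent_node[node]
    }
  } else if (!include_root && length(tip_idx) == 1) {
    # single tip without root path: just its terminal branch
    keep <- parent_edge[tip_idx]
    on_path[] <- FALSE
    on_path[keep] <- TRUE
  }
  sum(tree$edge.length[on_path])
}

#' Bray-Curtis dissimilarity
#'
#' `1 - 2 * sum(min(x, y)) / sum(x + y)`, in `[0, 1]`.
#'
#' @param x,y Non-negative abundance vectors of equal length, not both
#'   all-zero.
#' @return Dissimilarity in `[0, 1]`.
#' @examples
#' bray_curtis(c(2, 0, 1), c(1, 1, 0)) # 0.6
#' @export
bray_curtis <- function(x, y) {
  if (length(x) != length(y)) abort("`x` and `y` differ in length.")
  if (any(x < 0) || any(y < 0)) abort("Abundances must be non-negative.")
  tot <- sum(x) + sum(y)
  if (tot == 0) abort("Both vectors are all-zero.")
  1 - 2 * sum(pmin(x, y)) / tot
}

#' Bray-Curtis dissimilarity matrix over samples
#'
#' @param x A [rhizo_counts], `css_norm`, or abundance matrix (features x
#'   samples).
#' @return A symmetric `dist`-convertible matrix with zero diagonal.
#' @export
bray_curtis_matrix <- function(x) {
  m <- if (inherits(x, "css_norm")) x$normalized else count_matrix(x)
  d <- as.matrix(vegan::vegdist(t(m), method = "bray"))
  diag(d) <- 0
  d
}

#' Principal coordinate analysis (classical MDS)
#'
#' Classical scaling of the double-centred `-0.5 * D^2` matrix. Negative
#' eigenvalues are reported, not corrected.
#'
#' @param d A symmetric distance matrix (or `dist`).
#' @param k Number of axes to return (default all with positive eigenvalue,
#'   capped at n - 1).
#' @return A list of class `rhizo_pcoa`: `$coordinates` (tibble with
#'   `sample_id` and `PCo1..k`), `$eigenvalues`, `$rel_eigen` (relative to
#'   the sum of positive eigenvalues).
#' @export
pcoa <- function(d, k = NULL) {
  m <- as.matrix(d)
  if (nrow(m) != ncol(m) || max(abs(m - t(m))) > 1e-8) {
    abort("`d` must be a symmetric square distance matrix.")
  }
  n <- nrow(m)
  fit <- suppressWarnings(cmdscale(as.dist(m), k = n - 1, eig = TRUE))
  eig <- fit$eig
  pos <- sum(eig > 1e-12)
  k <- min(k %||% pos, max(pos, 1L))
  coords <- fit$points[, seq_len(k), drop = FALSE]
  colnames(coords) <- paste0("PCo", seq_len(k))
  ids <- rownames(m) %||% paste0("s", seq_len(n))
  structure(list(coordinates = as_tibble(cbind(tibble(sample_id = ids),
                                               as.data.frame(coords))),
                 eigenvalues = eig,
                 rel_eigen = eig / sum(eig[eig > 0])),
            class = "rhizo_pcoa")
}

#' @export
print.rhizo_pcoa <- function(x, ...) {
  cat(sprintf("<rhizo_pcoa> %d samples; first axes explain %s\n",
              nrow(x$coordinates),
              paste(sprintf("%.1f%%", 100 * head(x$rel_eigen, 3)), collapse = ", ")))
  invisible(x)
}

#' @rdname pcoa
#' @param x A `rhizo_pcoa` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.rhizo_pcoa <- function(x, ...) x$coordinates

#' Complete-linkage hierarchical clustering
#'
#' @param d A symmetric distance matrix (or `dist`), n >= 2.
#' @return An [stats::hclust] object (complete linkage).
#' @export
hclust_complete <- function(d) {
  m <- as.matrix(d)
  if (nrow(m) < 2) abort("Need at least 2 observations to cluster.")
  hclust(as.dist(m), method = "complete")
}

#' Spearman rank correlation against cycle number
#'
#' Rank correlation with mid-ranks for ties. The p value uses the
#' t-approximation by default; `exact = TRUE` requests the exact null
#' distribution (available for small n without ties).
#'
#' @param values Numeric vector (e.g. per-sample Shannon diversity).
#' @param cycle Numeric vector of equal length (>= 3).
#' @param exact Use the exact p when available (default FALSE:
#'   t-approximation).
#' @return A tibble with `rho`, `p`, `n`, `method`, `degenerate`.
#' @export
spearman_trend <- function(values, cycle, exact = FALSE) {
  if (length(values) != length(cycle)) abort("Input lengths differ.")
  if (length(values) < 3) abort("Need at least 3 observations.")
  if (sd(values) == 0 || sd(cycle) == 0) {
    return(tibble(rho = NA_real_, p = NA_real_, n = length(values),
                  method = "degenerate", degenerate = TRUE))
  }
  ct <- suppressWarnings(cor.test(values, cycle, method = "spearman",
                                  exact = exact, continuity = FALSE))
  tibble(rho = unname(ct$estimate), p = ct$p.value, n = length(values),
         method = if (exact) "exact" else "t-approximation",
         degenerate = FALSE)
}

#' Per-sample alpha diversity in tidy form
#'
#' Computes Shannon diversity, observed features and (when a tree is given)
#' Faith's PD for every sample, returning a long tibble joined to the sample
#' metadata.
#'
#' @param x A [rhizo_counts].
#' @param tree Optional [ape::phylo] covering all features.
#' @return A tibble: `sample_id`, `metric`, `value`, plus metadata columns.
#' @export
alpha_diversity <- function(x, tree = NULL) {
  stopifnot(inherits(x, "rhizo_counts"))
  m <- x$counts
  per_sample <- function(metric, f) {
    tibble(sample_id = colnames(m), metric = metric,
           value = vapply(seq_len(ncol(m)), function(j) f(m[, j]), numeric(1)))
  }
  out <- bind_rows(
    per_sample("shannon", shannon),
    per_sample("observed", function(v) as.numeric(observed_features(v))))
  if (!is.null(tree)) {
    missing <- setdiff(rownames(m), tree$tip.label)
    if (length(missing) > 0) {
      abort(paste0("Tree lacks tips for feature(s): ",
                   paste(head(missing, 10), collapse = ", ")))
    }
    out <- bind_rows(out, per_sample("faith_pd", function(v) {
      faith_pd(rownames(m)[v > 0], tree)
    }))
  }
  left_join(out, x$metadata, by = "sample_id")
}
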