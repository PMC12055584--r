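test_that("KW + rank LSD letters: hand statistic, shared letters, consistency", {
  # two identical groups share a letter
  res <- kruskal_wallis_lsd(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3),
                            alpha = 0.05)
  expect_equal(res$letters$letter[1], res$letters$letter[2])

  # hand-worked tie-corrected KW statistic for (4,4,4) vs (9,9,9): H = 5
  res2 <- kruskal_wallis_lsd(c(4, 4, 4, 9, 9, 9), rep(c("a", "b"), each = 3))
  expect_equal(res2$kw$statistic, 5, tolerance = 1e-12)
  # and it matches the standard implementation on a 3-group fixture
  v <- c(1, 5, 2, 8, 9, 7, 4, 3, 6, 10, 12, 11)
  g <- rep(c("x", "y", "z"), each = 4)
  expect_equal(kruskal_wallis_lsd(v, g)$kw$statistic,
               unname(kruskal.test(v, factor(g))$statistic))

  # letters consistent with the pairwise significance matrix
  set.seed(15)
  for (i in 1:5) {
    vals <- c(rnorm(5, 0), rnorm(5, 3), rnorm(5, 6), rnorm(5, 0.5))
    grp <- rep(c("g1", "g2", "g3", "g4"), each = 5)
    fit <- kruskal_wallis_lsd(vals, grp, alpha = 0.05)
    let <- setNames(fit$letters$letter, fit$letters$group)
    for (r in seq_len(nrow(fit$pairwise))) {
      shares <- any(strsplit(let[[fit$pairwise$group1[r]]], "")[[1]] %in%
                      strsplit(let[[fit$pairwise$group2[r]]], "")[[1]])
      sig <- fit$pairwise$padj[r] <= 0.05
      expect_equal(!shares, sig)
    }
  }
  expect_error(kruskal_wallis_lsd(1:3, c("a", "a", "b")), "< 2 observations")
})

test_that("Wilcoxon rank-sum: exact enumeration, symmetry, tie fallback", {
  res <- wilcoxon_rank_sum(c(4, 5, 6), c(1, 2, 3), "greater")
  expect_equal(res$p, 1 / 20)
  expect_equal(res$method, "exact")
  # two-sided p symmetric under swap
  x <- c(1.2, 3.4, 2.2, 5.1); y <- c(2.0, 4.4, 6.2)
  expect_equal(wilcoxon_rank_sum(x, y)$p, wilcoxon_rank_sum(y, x)$p)
  # ties force the normal approximation
  tied <- wilcoxon_rank_sum(c(1, 2, 2, 9, 9, 9, 10, 11, 12),
                            c(2, 2, 3, 9, 9, 9, 4, 5, 6))
  expect_equal(tied$method, "normal_approximation")
  expect_error(wilcoxon_rank_sum(numeric(0), 1:3), "non-empty")
})

test_that("Wilcoxon p values are calibrated under the null", {
  set.seed(16)
  n_sim <- 2000
  hits <- sum(vapply(seq_len(n_sim), function(i) {
    wilcoxon_rank_sum(rnorm(8), rnorm(8))$p < 0.05
  }, logical(1)))
  expect_gte(hits / n_sim, 0.03)
  expect_lte(hits / n_sim, 0.07)
})

test_that("ANOSIM separates clusters, respects the permutation floor, and is seedable", {
  # two tight, distant clusters: R = 1
  pts <- rbind(matrix(rnorm(10, 0, 0.01), 5), matrix(rnorm(10, 50, 0.01), 5))
  d <- as.matrix(dist(pts))
  g <- rep(c("a", "b"), each = 5)
  res <- anosim_test(d, g, n_perm = 999, seed = 4)
  expect_equal(res$R, 1)
  expect_gte(res$p, 1 / (999 + 1))
  res2 <- anosim_test(d, g, n_perm = 999, seed = 4)
  expect_identical(res, res2)
  expect_error(anosim_test(d, rep("a", 10)), ">= 2 groups")

  # random labels: R near zero
  set.seed(17)
  m <- matrix(rnorm(40), 20)
  dr <- as.matrix(dist(m))
  rr <- anosim_test(dr, rep(c("a", "b"), 10), n_perm = 199, seed = 1)
  expect_lt(abs(rr$R), 0.35)
  expect_gt(rr$p, 0.05)
})

test_that("PERMANOVA partitions variance for constructed fixtures", {
  pts <- rbind(matrix(rnorm(20, 0, 0.1), 10), matrix(rnorm(20, 30, 0.1), 10))
  d <- as.matrix(dist(pts))
  g <- rep(c("a", "b"), each = 10)
  res <- permanova_test(d, g, n_perm = 999, seed = 5)
  expect_gt(res$R2, 0.9)
  expect_gte(res$p, 1 / 1000)
  # identical groups: R2 near zero
  set.seed(18)
  d0 <- as.matrix(dist(matrix(rnorm(40), 20)))
  r0 <- permanova_test(d0, rep(c("a", "b"), 10), n_perm = 199, seed = 2)
  expect_lt(r0$R2, 0.2)
})

test_that("growth normalization subtracts the matching control means", {
  rec <- tibble::tibble(
    strains = rep(c("S1", "S1+H"), each = 6),
    focal_strain = "S1",
    carbon_source = rep(c("none", "none", "none", "sucrose", "sucrose", "sucrose"), 2),
    replicate = rep(1:3, 4),
    cfu = c(10, 20, 30, 100, 110, 90, 5, 5, 5, 200, 210, 190))
  norm <- normalize_growth(rec)
  expect_equal(norm$cfu_normalized[norm$strains == "S1" &
                                     norm$carbon_source == "sucrose"],
               c(80, 90, 70))
  expect_equal(norm$cfu_normalized[norm$strains == "S1+H" &
                                     norm$carbon_source == "sucrose"],
               c(195, 205, 185))
  # control-level growth normalizes to zero on average
  expect_equal(mean(norm$cfu_normalized[norm$carbon_source == "none" &
                                          norm$strains == "S1"]), 0)
  expect_error(normalize_growth(rec[rec$carbon_source != "none", ]), "S1")
})

test_that("facilitation test detects planted boosts and respects exchangeability", {
  expect_equal(facilitation_test(c(10, 11, 12), c(1, 2, 3))$p, 1 / 20)
  same <- facilitation_test(c(5, 7, 9, 6), c(5, 7, 9, 6))
  expect_gte(same$p, 0.5)
  set.seed(19)
  shifted <- facilitation_test(rnorm(6, 100, 1), rnorm(6, 10, 1))
  expect_lt(shifted$p, 0.05)
  expect_error(facilitation_test(c(1, 2), c(1, 2, 3)), ">= 3")
})
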