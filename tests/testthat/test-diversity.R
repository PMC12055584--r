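test_that("CSS factors match direct recomputation and preserve ratios", {
  # symmetry and scale equivariance
  m <- cbind(s1 = c(10L, 5L, 0L, 2L), s2 = c(10L, 5L, 0L, 2L))
  rownames(m) <- paste0("f", 1:4)
  res <- css_normalize(m, quantile = 0.5)
  expect_equal(res$scaling$factor[1], res$scaling$factor[2])
  expect_equal(res$normalized[, 1], res$normalized[, 2])
  m2 <- cbind(m, s3 = 2L * m[, 1])
  res2 <- css_normalize(m2, quantile = 0.5)
  expect_equal(res2$scaling$factor[3], 2 * res2$scaling$factor[1])
  expect_equal(res2$normalized[, 3], res2$normalized[, 1])

  # oracle: factors equal brute-force "sum of counts <= sample quantile"
  set.seed(7)
  for (i in 1:5) {
    r <- random_count_matrix(50, 6, lambda = 15)
    q <- c(0.25, 0.5, 0.75)[((i - 1) %% 3) + 1]
    res3 <- css_normalize(r, quantile = q)
    brute <- vapply(seq_len(ncol(r)), function(j) {
      cj <- r[, j]
      qv <- quantile(cj[cj > 0], q, type = 7, names = FALSE)
      sum(cj[cj <= qv])
    }, numeric(1))
    expect_equal(res3$scaling$factor, brute)
    expect_true(all(res3$scaling$factor > 0))
    # within-sample ratios of nonzero features preserved exactly
    j <- 1
    nz <- which(r[, j] > 0)
    ratios <- res3$normalized[nz, j] / r[nz, j]
    expect_equal(max(ratios) - min(ratios), 0)
  }
  expect_error(css_normalize(cbind(a = c(0L, 0L))), "All-zero")
})

test_that("Shannon diversity matches closed forms and bounds", {
  expect_equal(shannon(rep(1, 10)), log(10), tolerance = 1e-12)
  expect_equal(shannon(c(0, 7, 0)), 0)
  expect_equal(shannon(c(1, 1, 2)),
               -(0.25 * log(0.25) * 2 + 0.5 * log(0.5)), tolerance = 1e-12)
  expect_equal(shannon(c(1, 1, 1, 1), base = 2), 2)
  expect_error(shannon(c(0, 0)), "positive")
  # Shannon <= log(richness), equality iff uniform
  set.seed(1)
  for (i in 1:10) {
    v <- rpois(20, 5)
    if (sum(v) == 0) next
    expect_lte(shannon(v), log(observed_features(v)) + 1e-12)
  }
})

test_that("observed features counts nonzero entries", {
  expect_equal(observed_features(c(0, 0, 0)), 0)
  expect_equal(observed_features(c(1, 0, 2)), 2)
  set.seed(2)
  v <- rpois(100, 0.5)
  expect_equal(observed_features(v), sum(v != 0))
})

test_that("Faith's PD matches hand traversals and the independent implementation", {
  tr <- ape::read.tree(text = "((A:1,B:1):1,C:3):0;")
  expect_equal(faith_pd(c("A", "B"), tr), 3.0)
  expect_equal(faith_pd("A", tr), 2.0)
  expect_equal(faith_pd(c("A", "B", "C"), tr), sum(tr$edge.length))
  expect_equal(faith_pd(c("A", "B"), tr, include_root = FALSE), 2.0)
  expect_error(faith_pd("Z", tr), "Z")

  skip_if_not_installed("picante")
  set.seed(9)
  tree <- ape::rcoal(15, tip.label = sprintf("t%02d", 1:15))
  comm <- matrix(rbinom(3 * 15, 1, 0.6), nrow = 3,
                 dimnames = list(paste0("s", 1:3), tree$tip.label))
  comm[1, ] <- 1
  ref <- picante::pd(comm, tree, include.root = TRUE)$PD
  ours <- vapply(1:3, function(i) {
    faith_pd(colnames(comm)[comm[i, ] == 1], tree)
  }, numeric(1))
  expect_equal(ours, ref, tolerance = 1e-9)
})

test_that("Bray-Curtis matches the closed form and matrix properties", {
  expect_equal(bray_curtis(c(2, 0, 1), c(1, 1, 0)), 0.6)
  expect_equal(bray_curtis(c(3, 1), c(3, 1)), 0)
  expect_equal(bray_curtis(c(1, 0), c(0, 2)), 1)
  expect_error(bray_curtis(c(0, 0), c(0, 0)), "all-zero")

  set.seed(3)
  m <- random_count_matrix(25, 8)
  d <- bray_curtis_matrix(m)
  expect_equal(d, t(d))
  expect_true(all(diag(d) == 0))
  expect_true(all(d >= 0 & d <= 1))
  # pairwise formula agrees with the vegan-backed matrix (dual route)
  expect_equal(d[2, 5], bray_curtis(m[, 2], m[, 5]), tolerance = 1e-12)
})

test_that("PCoA reconstructs Euclidean configurations and flags asymmetry", {
  pts <- cbind(x = c(0, 3, 3, 10, -4), y = c(0, 0, 4, 5, 2))
  rownames(pts) <- paste0("p", 1:5)
  d <- as.matrix(dist(pts))
  fit <- pcoa(d)
  co <- as.matrix(fit$coordinates[, -1])
  rec <- as.matrix(dist(co[, 1:2]))
  expect_equal(unname(rec), unname(d), tolerance = 1e-9)

  # three equidistant points: two equal positive eigenvalues
  d3 <- matrix(1, 3, 3) - diag(3)
  f3 <- pcoa(d3)
  eig <- f3$eigenvalues[1:2]
  expect_equal(eig[1], eig[2], tolerance = 1e-9)
  expect_true(all(eig > 0))

  # duplicated point maps to identical coordinates
  d4 <- as.matrix(dist(rbind(pts, p6 = pts[1, ])))
  f4 <- pcoa(d4)
  c4 <- as.matrix(f4$coordinates[, -1])
  expect_equal(c4[1, ], c4[6, ], tolerance = 1e-9)

  bad <- matrix(c(0, 1, 2, 0), 2, 2)
  expect_error(pcoa(bad), "symmetric")
})

test_that("complete-linkage clustering matches hand agglomeration", {
  ids <- c("A", "B", "C", "D")
  d <- matrix(0, 4, 4, dimnames = list(ids, ids))
  d["A", "B"] <- d["B", "A"] <- 1
  d["C", "D"] <- d["D", "C"] <- 2
  d["A", "C"] <- d["C", "A"] <- 5
  d["A", "D"] <- d["D", "A"] <- 6
  d["B", "C"] <- d["C", "B"] <- 5.5
  d["B", "D"] <- d["D", "B"] <- 6.5
  h <- hclust_complete(d)
  # hand agglomeration: {A,B}@1, {C,D}@2, all@max(5,6,5.5,6.5)=6.5
  expect_equal(h$height, c(1, 2, 6.5))

  expect_error(hclust_complete(matrix(0, 1, 1)), "at least 2")
  set.seed(4)
  for (i in 1:5) {
    m <- random_count_matrix(10, 7)
    hh <- hclust_complete(bray_curtis_matrix(m))
    expect_true(all(diff(hh$height) >= -1e-12))
  }
})

test_that("Spearman trend handles ties, direction and degeneracy", {
  tr <- spearman_trend(c(9, 7, 5, 3), 1:4)
  expect_equal(tr$rho, -1)
  # mid-rank oracle for the tied case
  x <- c(1, 2, 2, 4); y <- 1:4
  rx <- rank(x); ry <- rank(y)
  rho_hand <- sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  expect_equal(spearman_trend(x, y)$rho, rho_hand, tolerance = 1e-12)
  deg <- spearman_trend(c(2, 2, 2), 1:3)
  expect_true(deg$degenerate)
  expect_true(is.na(deg$rho))
})

test_that("Spearman p values are calibrated under the null", {
  set.seed(10)
  n_sim <- 2000
  hits <- 0
  for (i in seq_len(n_sim)) {
    v <- rnorm(24)
    cyc <- rep(1:6, each = 4)
    if (spearman_trend(v, cyc)$p < 0.05) hits <- hits + 1
  }
  expect_gte(hits / n_sim, 0.03)
  expect_lte(hits / n_sim, 0.07)
})
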