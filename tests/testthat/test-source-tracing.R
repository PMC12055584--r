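test_that("prevalence filter uses a strict inequality at the boundary", {
  m <- matrix(0L, 3, 40, dimnames = list(c("one", "two", "common"),
                                         sprintf("s%02d", 1:40)))
  m["one", 1] <- 5L         # prevalence 1/40 = 0.025 < 0.05 -> removed
  m["two", 1:2] <- 5L       # prevalence 2/40 = 0.05, not < 0.05 -> kept
  m["common", ] <- 3L
  rc <- toy_counts(m, communities = rep("cycle_1", 40))
  f <- filter_features(rc, prevalence_min = 0.05)
  expect_setequal(rownames(f$counts), c("two", "common"))
  expect_equal(attr(f, "removed")$feature_id, "one")
})

test_that("lineage exclusion removes organellar features", {
  m <- random_count_matrix(3, 4)
  rc <- rhizo_counts(m, data.frame(sample_id = colnames(m), community = "x"),
                     taxonomy = data.frame(
                       feature_id = rownames(m),
                       lineage = c("Bacteria; Chloroplast", "Bacteria; Rhizobiaceae",
                                   "Bacteria; Mitochondria")))
  f <- filter_features(rc, prevalence_min = 0)
  expect_equal(rownames(f$counts), rownames(m)[2])
  expect_setequal(attr(f, "removed")$reason, "excluded_lineage")
})

test_that("filter survivors equal a brute-force recount on random fixtures", {
  set.seed(6)
  for (i in 1:5) {
    m <- random_count_matrix(40, 12, lambda = 0.6)
    m <- m[rowSums(m) >= 0, , drop = FALSE]
    rc <- toy_counts(m, communities = rep("x", 12))
    f <- filter_features(rc, prevalence_min = 0.25, excluded_lineages = character())
    brute <- rownames(m)[rowMeans(m > 0) >= 0.25]
    expect_setequal(rownames(f$counts), brute)
  }
})

test_that("exact matching is full-length identity only", {
  q <- c(q1 = "ACGT", q2 = "ACGA", q3 = "TTTT")
  r <- c(r1 = "ACGT", r2 = "TTTA")
  mm <- match_exact(q, r)
  expect_equal(mm$reference_id, c("r1", NA, NA))
  expect_error(match_exact(c(a = "AC", b = "AC"), r), "ambiguous")
})

test_that("source classification recovers simulator ground truth", {
  cfg <- small_config(rng_seed = 13)
  pool <- generate_taxon_pool(cfg)
  ds <- simulate_succession(pool, cfg)
  css <- css_normalize(ds$counts, quantile = 0.5)
  meta <- ds$counts$metadata
  pick <- function(cm) css$normalized[, meta$sample_id[meta$community == cm],
                                      drop = FALSE]
  seqs <- setNames(pool$taxa$sequence, pool$taxa$taxon_id)
  tr <- classify_sources(pick("cycle_6"), pick("soil_wash"), pick("sbrb"),
                         sequences = seqs)
  asg <- tr$assignments
  # partition and abundance accounting
  expect_equal(sum(tr$summary$n_features), nrow(asg))
  expect_equal(sum(tr$summary$rel_abund), 1, tolerance = 1e-9)
  # every label matches the origin table restricted to detection
  origin <- setNames(ds$origin$origin, ds$origin$taxon_id)
  soil_det <- rowMeans(pick("soil_wash")) > 0
  sbrb_det <- rowMeans(pick("sbrb")) > 0
  expected <- vapply(asg$asv_id, function(id) {
    s <- soil_det[id]; b <- sbrb_det[id]
    if (s && b) "shared" else if (s) "soil_only" else if (b) "sbrb_only" else "untraced"
  }, character(1))
  expect_equal(asg$label, unname(expected))
  # sbrb_only features are seed-exclusive taxa (ground truth)
  sb_ids <- asg$asv_id[asg$label == "sbrb_only"]
  expect_true(all(origin[sb_ids] == "seed"))
  sh_ids <- asg$asv_id[asg$label == "shared"]
  expect_true(all(origin[sh_ids] == "both"))
})

test_that("emergence counts equal a brute-force double loop and are monotone", {
  set.seed(8)
  make_tables <- function() {
    lapply(1:4, function(i) random_count_matrix(30, 3, lambda = 0.8))
  }
  for (rep in 1:5) {
    tabs <- make_tables()
    names(tabs) <- paste0("c", 0:3)
    th <- c(0, 1e-4, 1e-3, 1e-2)
    curves <- emergence_curves(tabs, th)
    # brute force
    rel <- lapply(tabs, function(m) rowMeans(sweep(m, 2, colSums(m), "/")))
    for (t in th) {
      for (ci in seq_along(tabs)) {
        brute <- 0
        for (f in rownames(tabs[[1]])) {
          det <- vapply(rel, function(v) v[f] >= t, logical(1))
          if (det[ci] && !any(det[seq_len(ci - 1)])) brute <- brute + 1
        }
        got <- curves$n_new[curves$threshold == t & curves$cycle_index == ci - 1]
        expect_equal(got, brute)
      }
    }
    # monotonicity: higher threshold never increases cumulative emergence
    for (i in seq_len(length(th) - 1)) {
      lo <- cumsum(curves$n_new[curves$threshold == th[i]])
      hi <- cumsum(curves$n_new[curves$threshold == th[i + 1]])
      expect_true(all(hi <= lo))
    }
  }
  # single table: every detected feature is new there
  single <- list(only = random_count_matrix(10, 2))
  cv <- emergence_curves(single, 1e-6)
  rel1 <- rowMeans(sweep(single$only, 2, colSums(single$only), "/"))
  expect_equal(cv$n_new, sum(rel1 >= 1e-6))
  expect_error(emergence_curves(single, numeric(0)), "non-empty")
})

test_that("a feature always present is new at cycle 0 only under threshold 0", {
  tabs <- lapply(1:3, function(i) {
    m <- random_count_matrix(5, 2, lambda = 10)
    m[1, ] <- 50L
    m
  })
  names(tabs) <- paste0("c", 0:2)
  cv <- emergence_curves(tabs, 0)
  expect_equal(cv$n_new[cv$cycle_index == 0], 5L)  # all detected at baseline
  expect_true(all(cv$n_new[cv$cycle_index > 0] == 0))
})
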