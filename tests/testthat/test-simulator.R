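test_that("taxon pool respects set arithmetic, flags and normalization", {
  cfg <- succession_config(n_soil_taxa = 5, n_seed_taxa = 3, n_shared_taxa = 1,
                           rng_seed = 3)
  pool <- generate_taxon_pool(cfg)
  taxa <- pool$taxa
  expect_equal(nrow(taxa), 7)
  expect_equal(sum(taxa$in_soil & taxa$in_seed), 1)
  expect_true(all(taxa$in_soil | taxa$in_seed))
  expect_equal(sum(taxa$soil_freq), 1, tolerance = 1e-9)
  expect_equal(sum(taxa$seed_freq), 1, tolerance = 1e-9)
  expect_true(all(taxa$fitness > 0))
  expect_false(anyDuplicated(taxa$sequence) > 0)
  expect_true(all(nchar(taxa$sequence) == cfg$seq_length))
  expect_setequal(pool$tree$tip.label, taxa$taxon_id)
})

test_that("zero seed fitness advantage leaves pools exchangeable, and pools are reproducible", {
  cfg <- succession_config(fitness_advantage_seed = 0, rng_seed = 11)
  p1 <- generate_taxon_pool(cfg)
  p2 <- generate_taxon_pool(cfg)
  expect_identical(p1$taxa, p2$taxa)
  expect_identical(ape::write.tree(p1$tree), ape::write.tree(p2$tree))
  # with a zero offset the seed flag carries no fitness multiplier
  expect_equal(median(p1$taxa$fitness[p1$taxa$in_seed]),
               median(p1$taxa$fitness), tolerance = 0.5)
})

test_that("replicator growth matches closed forms", {
  expect_equal(simulate_growth(c(0.5, 0.5), c(2, 1), 1), c(2 / 3, 1 / 3))
  x <- c(0.2, 0.3, 0.5)
  expect_equal(simulate_growth(x, c(3, 3, 3), 7), x)     # equal fitness
  expect_equal(simulate_growth(x, c(2, 9, 4), 0), x)     # g = 0 identity
  expect_equal(sum(simulate_growth(x, c(2, 1, 5), 12)), 1)
  expect_error(simulate_growth(c(0.5, 0.5), c(1, -1), 1), "positive")
  expect_error(simulate_growth(c(0.7, 0.5), c(1, 1), 1), "sum to 1")
})

test_that("multinomial sampling conserves depth and matches binomial spread", {
  set.seed(42)
  expect_equal(sample_reads(c(1, 0), 100), c(100L, 0L))
  for (i in 1:20) {
    f <- runif(5); f <- f / sum(f)
    expect_equal(sum(sample_reads(f, 1234L)), 1234L)
  }
  # uniform over 4 taxa at depth 1e6: each count within 5 binomial s.d.
  draw <- sample_reads(rep(0.25, 4), 1e6L)
  sd_bin <- sqrt(1e6 * 0.25 * 0.75)
  expect_true(all(abs(draw - 250000) < 5 * sd_bin))
  expect_error(sample_reads(c(0.5, 0.5), 0), "> 0")
})

test_that("succession emits the full design and honors degenerate mixing", {
  cfg <- small_config(rng_seed = 2)
  pool <- generate_taxon_pool(cfg)
  ds <- simulate_succession(pool, cfg)
  meta <- ds$counts$metadata
  expect_setequal(unique(meta$community),
                  c("soil_wash", paste0("cycle_", 1:6), "sbrb", "recovered"))
  expect_true(all(table(meta$community) == cfg$n_replicates))
  # conservation: every rhizosphere sample sums to seq_depth
  cyc_cols <- meta$sample_id[grepl("^cycle_", meta$community)]
  expect_true(all(colSums(ds$counts$counts[, cyc_cols]) == cfg$seq_depth))
  # ground-truth closure
  nonzero <- rownames(ds$counts$counts)[rowSums(ds$counts$counts) > 0]
  expect_true(all(nonzero %in% ds$origin$taxon_id))

  # no seed input and no shared taxa: seed-exclusive taxa never appear in cycles
  cfg0 <- small_config(rng_seed = 2, seed_input_load = 0, n_shared_taxa = 0)
  ds0 <- simulate_succession(generate_taxon_pool(cfg0), cfg0)
  seed_only <- ds0$origin$taxon_id[ds0$origin$origin == "seed"]
  cyc_cols0 <- ds0$counts$metadata$sample_id[grepl("^cycle_",
                                                   ds0$counts$metadata$community)]
  expect_true(all(ds0$counts$counts[seed_only, cyc_cols0] == 0))
})

test_that("determinism: same config and seed give byte-identical datasets", {
  cfg <- small_config(rng_seed = 9)
  d1 <- simulate_succession(generate_taxon_pool(cfg), cfg)
  d2 <- simulate_succession(generate_taxon_pool(cfg), cfg)
  expect_identical(d1$counts$counts, d2$counts$counts)
  expect_identical(d1$origin, d2$origin)
  f1 <- generate_function_table(n_per_class = 5, rng_seed = 4)
  f2 <- generate_function_table(n_per_class = 5, rng_seed = 4)
  expect_identical(f1$counts$counts, f2$counts$counts)
  m1 <- generate_mag_dataset(rng_seed = 4)
  m2 <- generate_mag_dataset(rng_seed = 4)
  expect_identical(m1$mags, m2$mags)
})

test_that("stronger seed fitness advantage increases the cycle-6 seed share", {
  seed_share <- function(adv, seed) {
    cfg <- small_config(rng_seed = seed, fitness_advantage_seed = adv)
    ds <- simulate_succession(generate_taxon_pool(cfg), cfg)
    meta <- ds$counts$metadata
    final <- meta$sample_id[meta$community == "cycle_6"]
    m <- ds$counts$counts[, final]
    seed_taxa <- ds$origin$taxon_id[ds$origin$origin != "soil"]
    sum(m[seed_taxa, ]) / sum(m)
  }
  s0 <- seed_share(0, 21)
  s2 <- seed_share(2, 21)
  expect_gt(s2, s0)
})

test_that("planted function classes have the configured expected fold change", {
  fn <- generate_function_table(n_per_class = 30, fold_change = 16, rng_seed = 8)
  mu <- fn$expected_mu
  bal <- fn$truth$kegg_id[fn$truth$class == "balanced"]
  expect_true(all(mu[bal, "rhizcom"] == mu[bal, "soil"]))
  enr <- fn$truth$kegg_id[fn$truth$class == "enriched_rhizcom"]
  expect_equal(unname(mu[enr, "rhizcom"] / mu[enr, "sbrb"]), rep(16, length(enr)))
  # realized group means approach the planted ratio (law of large numbers)
  cm <- fn$counts$metadata
  rz <- rowMeans(fn$counts$counts[enr, cm$sample_id[cm$community == "rhizcom"]])
  sb <- rowMeans(fn$counts$counts[enr, cm$sample_id[cm$community == "sbrb"]])
  expect_equal(median(rz / sb), 16, tolerance = 0.35)
  expect_error(generate_function_table(fold_change = 0), "> 0")
})

test_that("MAG generator plants quality, uniqueness and vitamin structure", {
  mg <- generate_mag_dataset(rng_seed = 12)
  expect_equal(nrow(mg$mags), 45)
  ann <- annotate_mags(mg$mags)
  # planted non-multi MAGs are uniquely assigned to their planted community
  uni <- !mg$truth$multi
  expect_true(all(lengths(ann$assigned[uni]) == 1))
  expect_equal(unlist(ann$assigned[uni]), mg$truth$true_community[uni],
               ignore_attr = TRUE)
  # seed-community MAGs carry complete riboflavin routes more often than soil
  rules <- default_reaction_rules()
  complete_ribo <- vapply(mg$mags$reactions,
                          function(r) pathway_complete(r, rules$riboflavin)$complete,
                          logical(1))
  n_sbrb <- sum(complete_ribo & mg$truth$true_community == "sbrb")
  n_soil <- sum(complete_ribo & mg$truth$true_community == "soil")
  expect_gt(n_sbrb / sum(mg$truth$true_community == "sbrb"),
            n_soil / sum(mg$truth$true_community == "soil"))
})

test_that("growth generator plants facilitation on disaccharides only", {
  gt <- generate_growth_table(rng_seed = 3)
  truth <- attr(gt, "truth")
  norm <- normalize_growth(gt)
  co <- norm[grepl("\\+", norm$strains) & norm$carbon_source == "sucrose" &
               norm$focal_strain == "DGS2", ]
  mono <- norm[!grepl("\\+", norm$strains) & norm$carbon_source == "sucrose" &
                 norm$focal_strain == "DGS2", ]
  expect_gt(mean(co$cfu_normalized), mean(mono$cfu_normalized))
  expect_true(all(truth$facilitated[truth$carbon_source == "sucrose"]))
  expect_false(any(truth$facilitated[truth$carbon_source == "glucose"]))
})
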