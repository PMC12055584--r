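# Independent truth-table oracle for the dominance rule, written from the
# pair-membership perspective: count, for each community, how many of its two
# comparisons it wins (is significantly higher) and how many it loses.
oracle_dominance <- function(o_rs, o_ro, o_so) {
  pairs <- list(c("rhizcom", "sbrb"), c("rhizcom", "soil"), c("sbrb", "soil"))
  outs <- c(o_rs, o_ro, o_so)
  wins <- c(rhizcom = 0, sbrb = 0, soil = 0)
  losses <- c(rhizcom = 0, sbrb = 0, soil = 0)
  for (i in 1:3) {
    a <- pairs[[i]][1]; b <- pairs[[i]][2]
    if (outs[i] == "A_higher") { wins[a] <- wins[a] + 1; losses[b] <- losses[b] + 1 }
    if (outs[i] == "B_higher") { wins[b] <- wins[b] + 1; losses[a] <- losses[a] + 1 }
  }
  enr <- names(wins)[wins == 2]
  if (length(enr) == 1) return(paste0("enriched_", enr))
  sup <- names(losses)[losses == 2]
  if (length(sup) == 1) return(paste0("suppressed_", sup))
  "balanced"
}

test_that("dominance classification agrees with the 27-case truth table", {
  states <- c("A_higher", "B_higher", "ns")
  grid <- expand.grid(rs = states, ro = states, so = states,
                      stringsAsFactors = FALSE)
  got <- dominance_classify(grid$rs, grid$ro, grid$so)
  want <- mapply(oracle_dominance, grid$rs, grid$ro, grid$so)
  expect_equal(got, unname(want))
  # totality and mutual exclusivity: exactly one category per vector
  expect_equal(length(got), 27)
  expect_true(all(got %in% c(paste0("enriched_", c("rhizcom", "sbrb", "soil")),
                             paste0("suppressed_", c("rhizcom", "sbrb", "soil")),
                             "balanced")))
})

test_that("named dominance cases follow the published rule", {
  # community higher in both its comparisons, third pair ns -> enriched
  expect_equal(dominance_classify("A_higher", "A_higher", "ns"),
               "enriched_rhizcom")
  expect_equal(dominance_classify("ns", "ns", "ns"), "balanced")
  # community lower in both its comparisons -> suppressed
  expect_equal(dominance_classify("B_higher", "B_higher", "ns"),
               "suppressed_rhizcom")
  expect_error(dominance_classify("up", "ns", "ns"), "Outcomes")
})

test_that("permuting community labels permutes categories correspondingly", {
  states <- c("A_higher", "B_higher", "ns")
  grid <- expand.grid(rs = states, ro = states, so = states,
                      stringsAsFactors = FALSE)
  base <- dominance_classify(grid$rs, grid$ro, grid$so)
  # swap sbrb <-> soil: pair (r,s)->(r,o), (r,o)->(r,s), (s,o) flips direction
  flip <- function(o) ifelse(o == "A_higher", "B_higher",
                             ifelse(o == "B_higher", "A_higher", "ns"))
  swapped <- dominance_classify(grid$ro, grid$rs, flip(grid$so))
  relabel <- c(enriched_rhizcom = "enriched_rhizcom",
               enriched_sbrb = "enriched_soil", enriched_soil = "enriched_sbrb",
               suppressed_rhizcom = "suppressed_rhizcom",
               suppressed_sbrb = "suppressed_soil",
               suppressed_soil = "suppressed_sbrb", balanced = "balanced")
  expect_equal(swapped, unname(relabel[base]))
})

test_that("ternary coordinates normalize and apply the mean-TPM filter", {
  tc <- ternary_coords(tibble::tibble(kegg_id = c("k1", "k2", "k3"),
                                      rhizcom = c(10, 0.2, 2),
                                      sbrb = c(10, 0.2, 1),
                                      soil = c(10, 0.2, 1)))
  expect_equal(unlist(tc[1, c("tern_rhizcom", "tern_sbrb", "tern_soil")]),
               rep(1 / 3, 3), ignore_attr = TRUE)
  expect_false(tc$included[2])   # mean 0.2 <= 0.5 -> excluded
  expect_equal(unlist(tc[3, c("tern_rhizcom", "tern_sbrb", "tern_soil")]),
               c(0.5, 0.25, 0.25), ignore_attr = TRUE)
  sums <- rowSums(tc[tc$included, c("tern_rhizcom", "tern_sbrb", "tern_soil")])
  expect_equal(sums, rep(1, sum(tc$included)), tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("planted enriched functions are recovered from the full DA chain", {
  fn <- generate_function_table(n_per_class = 20, fold_change = 16, rng_seed = 17)
  fc <- fn$counts
  pairs <- list(c("rhizcom", "sbrb"), c("rhizcom", "soil"), c("sbrb", "soil"))
  das <- lapply(pairs, function(pr) {
    keep <- fc$metadata$community %in% pr
    nb_wald(fc$counts[, keep], fc$metadata$community[keep],
            group_a = pr[1], group_b = pr[2], min_total = 1000)
  })
  cm <- fc$metadata
  mean_tpm <- vapply(c("rhizcom", "sbrb", "soil"), function(x) {
    rowMeans(fn$tpm[, cm$sample_id[cm$community == x], drop = FALSE])
  }, numeric(nrow(fn$tpm)))
  dom <- dominance_records(das[[1]], das[[2]], das[[3]],
                           tibble::as_tibble(cbind(
                             data.frame(kegg_id = rownames(fn$tpm)), mean_tpm)))
  j <- merge(dom, fn$truth, by = "kegg_id")
  enr <- j[startsWith(j$class, "enriched") & j$included, ]
  expect_gte(mean(enr$category == enr$class), 0.9)
})

test_that("hierarchy fractions sum to one and match hand counts", {
  rec <- tibble::tibble(kegg_id = paste0("k", 1:5),
                        category = c("balanced", "balanced", "enriched_sbrb",
                                     "balanced", "enriched_soil"))
  bm <- tibble::tibble(kegg_id = paste0("k", 1:4),
                       hierarchy = c("H1", "H1", "H1", "H2"))
  hf <- hierarchy_fractions(rec, bm)
  h1 <- hf[hf$hierarchy == "H1", ]
  expect_equal(h1$fraction[h1$category == "balanced"], 2 / 3)
  expect_equal(h1$fraction[h1$category == "enriched_sbrb"], 1 / 3)
  expect_equal(hf$hierarchy[hf$category == "enriched_soil"], "unmapped")
  agg <- tapply(hf$fraction, hf$hierarchy, sum)
  expect_equal(as.numeric(agg), rep(1, length(agg)))
})
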