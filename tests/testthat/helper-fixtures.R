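# Shared fixture builders. All fixtures are generated in code; tests that
# need randomness seed their own stream locally.

toy_counts <- function(m = NULL, communities = NULL) {
  if (is.null(m)) {
    m <- matrix(c(5L, 0L, 3L, 2L, 1L, 4L), nrow = 3,
                dimnames = list(c("ASV1", "ASV2", "ASV3"), c("s1", "s2")))
  }
  communities <- communities %||% rep("cycle_1", ncol(m))
  rhizo_counts(m, data.frame(sample_id = colnames(m), community = communities,
                             cycle = 1L, replicate = seq_len(ncol(m))))
}

random_count_matrix <- function(n_feat, n_samp, lambda = 20) {
  m <- matrix(rpois(n_feat * n_samp, lambda), n_feat, n_samp,
              dimnames = list(sprintf("f%03d", seq_len(n_feat)),
                              sprintf("s%02d", seq_len(n_samp))))
  storage.mode(m) <- "integer"
  m
}

small_config <- function(rng_seed = 1L, ...) {
  args <- list(rng_seed = rng_seed, seq_depth = 2e4L, depth_soil_wash = 2e4L,
               n_soil_taxa = 40L, n_seed_taxa = 8L, n_shared_taxa = 2L)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(succession_config, args)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
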