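#' Configuration for the serial-propagation community simulator
#'
#' Bundles every parameter of the synthetic study: two source pools (a
#' taxon-rich soil wash and a small but fit seed-borne pool), serial
#' propagation with repeated seed input, within-cycle replicator growth and
#' multinomial sequencing noise. Defaults mirror the microcosm design the
#' package targets: 6 propagation cycles with 4 replicate rhizospheres each.
#'
#' @param n_cycles Number of propagation cycles (default 6).
#' @param n_replicates Replicate rhizospheres per sampled community (default 4).
#' @param seq_depth Reads per rhizosphere sample (default 1e5; sequencing
#'   depth is a free choice of the synthetic design).
#' @param generations_per_cycle Bacterial generations of within-cycle growth.
#' @param transfer_fraction Proportion of the inoculum contributed by the
#'   carried previous-cycle community.
#' @param seed_input_load Proportion contributed fresh by seed-borne bacteria
#'   at every cycle (the seeds are present in each new plant).
#' @param n_soil_taxa,n_seed_taxa,n_shared_taxa Pool sizes; shared taxa are
#'   members of both pools.
#' @param fitness_advantage_seed Log2-scale fitness offset of seed-pool
#'   members (seed taxa are few but rhizosphere-adapted).
#' @param depth_soil_wash Reads per soil-wash sample.
#' @param seq_length ASV sequence length in nt (V3-V4-like, default 250).
#' @param fitness_sdlog Log-sd of the baseline log-normal fitness draw.
#' @param freq_sdlog Log-sd of the log-normal source-frequency draws.
#' @param rng_seed Integer seed; identical configs give byte-identical
#'   datasets.
#' @return A list of class `succession_config`.
#' @export
succession_config <- function(n_cycles = 6L, n_replicates = 4L,
                              seq_depth = 1e5L, generations_per_cycle = 5L,
                              transfer_fraction = 0.1, seed_input_load = 0.05,
                              n_soil_taxa = 80L, n_seed_taxa = 12L,
                              n_shared_taxa = 2L, fitness_advantage_seed = 1,
                              depth_soil_wash = 1e5L, seq_length = 250L,
                              fitness_sdlog = 0.3, freq_sdlog = 1,
                              rng_seed = 1L) {
  cfg <- list(n_cycles = as.integer(n_cycles),
              n_replicates = as.integer(n_replicates),
              seq_depth = as.integer(seq_depth),
              generations_per_cycle = as.integer(generations_per_cycle),
              transfer_fraction = transfer_fraction,
              seed_input_load = seed_input_load,
              n_soil_taxa = as.integer(n_soil_taxa),
              n_seed_taxa = as.integer(n_seed_taxa),
              n_shared_taxa = as.integer(n_shared_taxa),
              fitness_advantage_seed = fitness_advantage_seed,
              depth_soil_wash = as.integer(depth_soil_wash),
              seq_length = as.integer(seq_length),
              fitness_sdlog = fitness_sdlog,
              freq_sdlog = freq_sdlog,
              rng_seed = as.integer(rng_seed))
  if (cfg$n_cycles < 1L) abort("`n_cycles` must be >= 1.")
  if (cfg$seq_depth <= 0L || cfg$depth_soil_wash <= 0L) abort("depths must be > 0.")
  props <- c(cfg$transfer_fraction, cfg$seed_input_load)
  if (any(props < 0 | props > 1)) abort("proportions must lie in [0, 1].")
  if (cfg$n_soil_taxa < 1L || cfg$n_seed_taxa < 1L) abort("taxon counts must be >= 1.")
  if (cfg$n_shared_taxa > min(cfg$n_soil_taxa, cfg$n_seed_taxa)) {
    abort("`n_shared_taxa` cannot exceed either pool size.")
  }
  structure(cfg, class = "succession_config")
}

# Run fn with a private, restorable RNG stream seeded at `seed + offset`.
# Offsets give each generator a documented position in the dataset's stream:
# pool 0, succession 1, functions 2, MAGs 3, growth 4.
with_sim_rng <- function(seed, offset, fn) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed((as.integer(seed) + as.integer(offset)) %% .Machine$integer.max)
  fn()
}

random_sequences <- function(n, len, max_tries = 100L) {
  seqs <- character(0)
  tries <- 0L
  while (length(seqs) < n) {
    need <- n - length(seqs)
    fresh <- vapply(seq_len(need), function(i) {
      paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
    }, character(1))
    seqs <- unique(c(seqs, fresh))
    tries <- tries + 1L
    if (tries > max_tries) {
      abort(sprintf(
        "Could not draw %d unique %d-nt sequences after %d rounds of rejection.",
        n, len, max_tries))
    }
  }
  seqs[seq_len(n)]
}

fake_lineage <- function(i, phylum) {
  sprintf("p__%s; c__Class_%02d; o__Order_%02d; f__Family_%02d; g__Genus_%03d",
          phylum, (i %% 7L) + 1L, (i %% 13L) + 1L, (i %% 23L) + 1L, i)
}

#' Generate the two-pool taxon universe
#'
#' Draws `n_soil_taxa + n_seed_taxa - n_shared_taxa` taxa with source
#' membership flags, log-normal within-pool frequencies (normalized to sum to
#' one per pool), log-normal fitness with the seed pool shifted up by
#' `2^fitness_advantage_seed`, unique random ASV sequences and a random
#' coalescent phylogeny over all taxa.
#'
#' @param config A [succession_config()].
#' @return A list of class `taxon_pool`: `$taxa` (tibble with columns
#'   `taxon_id`, `in_soil`, `in_seed`, `soil_freq`, `seed_freq`, `fitness`,
#'   `sequence`, `lineage`, `tip_label`) and `$tree` (an [ape::phylo]).
#' @export
generate_taxon_pool <- function(config) {
  stopifnot(inherits(config, "succession_config"))
  with_sim_rng(config$rng_seed, 0L, function() {
    n_total <- config$n_soil_taxa + config$n_seed_taxa - config$n_shared_taxa
    ids <- sprintf("ASV%04d", seq_len(n_total))
    # layout: [soil-only | shared | seed-only]
    in_soil <- seq_len(n_total) <= config$n_soil_taxa
    in_seed <- seq_len(n_total) > (config$n_soil_taxa - config$n_shared_taxa)

    soil_freq <- rep(0, n_total)
    soil_freq[in_soil] <- rlnorm(sum(in_soil), 0, config$freq_sdlog)
    soil_freq <- soil_freq / sum(soil_freq)
    seed_freq <- rep(0, n_total)
    seed_freq[in_seed] <- rlnorm(sum(in_seed), 0, config$freq_sdlog)
    seed_freq <- seed_freq / sum(seed_freq)

    fitness <- rlnorm(n_total, 0, config$fitness_sdlog)
    fitness[in_seed] <- fitness[in_seed] * 2^config$fitness_advantage_seed

    sequences <- random_sequences(n_total, config$seq_length)
    phyla <- c("Proteobacteria", "Bacteroidota", "Firmicutes",
               "Verrucomicrobiota", "Actinomycetota")
    lineage <- vapply(seq_len(n_total), function(i) {
      fake_lineage(i, phyla[(i %% length(phyla)) + 1L])
    }, character(1))

    tree <- ape::rcoal(n_total, tip.label = sample(ids))

    taxa <- tibble(taxon_id = ids, in_soil = in_soil, in_seed = in_seed,
                   soil_freq = soil_freq, seed_freq = seed_freq,
                   fitness = fitness, sequence = sequences,
                   lineage = lineage, tip_label = ids)
    structure(list(taxa = taxa, tree = tree, config = config),
              class = "taxon_pool")
  })
}

#' @export
print.taxon_pool <- function(x, ...) {
  cat(sprintf("<taxon_pool> %d taxa (%d soil, %d seed, %d shared)\n",
              nrow(x$taxa), sum(x$taxa$in_soil), sum(x$taxa$in_seed),
              sum(x$taxa$in_soil & x$taxa$in_seed)))
  invisible(x)
}

#' Discrete replicator growth
#'
#' Propagates relative frequencies through `generations` rounds of
#' fitness-proportional growth: `x_i w_i^g / sum_j x_j w_j^g`. This is the
#' simulator's within-cycle dynamic: constant per-taxon fitness, no
#' interaction terms.
#'
#' @param freqs Non-negative frequency vector summing to 1.
#' @param fitness Positive per-generation growth weights, same length.
#' @param generations Integer >= 0.
#' @return A frequency vector summing to 1.
#' @examples
#' simulate_growth(c(0.5, 0.5), c(2, 1), 1) # -> c(2/3, 1/3)
#' @export
simulate_growth <- function(freqs, fitness, generations) {
  if (length(freqs) != length(fitness)) abort("`freqs` and `fitness` differ in length.")
  if (any(freqs < 0)) abort("`freqs` must be non-negative.")
  if (abs(sum(freqs) - 1) > 1e-8) abort("`freqs` must sum to 1.")
  if (any(fitness <= 0)) abort("`fitness` must be positive.")
  if (generations < 0) abort("`generations` must be >= 0.")
  # log-space for numerical stability at large g
  lw <- log(freqs) + generations * log(fitness)
  lw[freqs == 0] <- -Inf
  w <- exp(lw - max(lw[is.finite(lw)]))
  w / sum(w)
}

#' Multinomial sequencing noise
#'
#' @param freqs Frequency vector summing to 1.
#' @param depth Total reads to draw (> 0).
#' @return Integer count vector summing to `depth`.
#' @export
sample_reads <- function(freqs, depth) {
  if (depth <= 0) abort("`depth` must be > 0.")
  if (abs(sum(freqs) - 1) > 1e-8) abort("`freqs` must sum to 1.")
  as.integer(rmultinom(1, depth, freqs)[, 1])
}

#' Simulate a full serial-propagation experiment
#'
#' Emits soil-wash replicates (multinomial draws from the soil pool), SbRB
#' replicates (seed pool after within-cycle growth, no soil input),
#' propagation cycles 1..n (inoculum = `transfer_fraction` x carried
#' previous-cycle mean frequencies + `seed_input_load` x seed frequencies,
#' renormalized, then replicator growth, then per-replicate multinomial
#' sequencing; cycle 1 carries the soil wash), and a recovered-community
#' sample set re-drawn from the cycle-n frequencies.
#'
#' @param pool A [generate_taxon_pool()] result.
#' @param config A [succession_config()]; defaults to the pool's config.
#' @return A list of class `succession_dataset`: `$counts` ([rhizo_counts]
#'   over all samples), `$origin` (tibble `taxon_id`, `origin` in
#'   soil/seed/both), `$pool`, and `$true_freqs` (matrix of the post-growth
#'   community frequencies per cycle, ground truth for the sampling step).
#' @export
simulate_succession <- function(pool, config = pool$config) {
  stopifnot(inherits(pool, "taxon_pool"), inherits(config, "succession_config"))
  taxa <- pool$taxa
  n <- nrow(taxa)
  with_sim_rng(config$rng_seed, 1L, function() {
    draw_set <- function(freqs, depth, label) {
      m <- vapply(seq_len(config$n_replicates),
                  function(r) sample_reads(freqs, depth), integer(n))
      colnames(m) <- sprintf("%s_r%d", label, seq_len(config$n_replicates))
      m
    }

    soil_wash <- draw_set(taxa$soil_freq, config$depth_soil_wash, "soil_wash")
    sbrb_freq <- simulate_growth(taxa$seed_freq, taxa$fitness,
                                 config$generations_per_cycle)
    sbrb <- draw_set(sbrb_freq, config$seq_depth, "sbrb")

    blocks <- list(soil_wash = soil_wash)
    true_freqs <- matrix(NA_real_, n, config$n_cycles,
                         dimnames = list(taxa$taxon_id,
                                         sprintf("cycle_%d", seq_len(config$n_cycles))))
    carried <- rowMeans(sweep(soil_wash, 2, colSums(soil_wash), "/"))
    for (cy in seq_len(config$n_cycles)) {
      inoc <- config$transfer_fraction * carried +
        config$seed_input_load * taxa$seed_freq
      if (sum(inoc) == 0) abort("Empty inoculum: both transfer terms are zero.")
      inoc <- inoc / sum(inoc)
      grown <- simulate_growth(inoc, taxa$fitness, config$generations_per_cycle)
      true_freqs[, cy] <- grown
      block <- draw_set(grown, config$seq_depth, sprintf("cycle_%d", cy))
      blocks[[sprintf("cycle_%d", cy)]] <- block
      carried <- rowMeans(sweep(block, 2, colSums(block), "/"))
    }
    blocks$sbrb <- sbrb
    blocks$recovered <- draw_set(true_freqs[, config$n_cycles],
                                 config$seq_depth, "recovered")

    counts <- do.call(cbind, blocks)
    rownames(counts) <- taxa$taxon_id
    community <- rep(names(blocks), vapply(blocks, ncol, integer(1)))
    cycle_num <- suppressWarnings(as.integer(sub("^cycle_", "", community)))
    meta <- tibble(sample_id = colnames(counts),
                   community = community,
                   cycle = dplyr::case_when(
                     community == "soil_wash" ~ 0L,
                     grepl("^cycle_", community) ~ cycle_num,
                     TRUE ~ NA_integer_),
                   replicate = as.integer(sub(".*_r", "", colnames(counts))))
    taxonomy <- tibble(feature_id = taxa$taxon_id, lineage = taxa$lineage)
    origin <- tibble(taxon_id = taxa$taxon_id,
                     origin = dplyr::case_when(
                       taxa$in_soil & taxa$in_seed ~ "both",
                       taxa$in_soil ~ "soil",
                       TRUE ~ "seed"))
    structure(list(counts = rhizo_counts(counts, meta, taxonomy),
                   origin = origin, pool = pool, true_freqs = true_freqs,
                   config = config),
              class = "succession_dataset")
  })
}

#' @export
print.succession_dataset <- function(x, ...) {
  cat(sprintf("<succession_dataset> %d taxa, %d samples (%d cycles x %d replicates)\n",
              nrow(x$counts$counts), ncol(x$counts$counts),
              x$config$n_cycles, x$config$n_replicates))
  invisible(x)
}

#' Generate a KEGG function abundance table with planted truth
#'
#' Draws negative-binomially distributed counts for functions in seven
#' planted classes: enriched in one of the three communities (RhizCom, SbRB,
#' soil; fold change `fold_change` up in that community), suppressed in one
#' (fold down), or balanced. A TPM table (per-sample scaling to 1e6) and the
#' truth labels are returned alongside the counts.
#'
#' @param n_per_class Functions per planted class (7 classes).
#' @param n_replicates Metagenome replicates per community (default 3).
#' @param base_mean Mean count of an unperturbed function.
#' @param fold_change Planted fold change (> 1).
#' @param dispersion NB dispersion (variance = mu + dispersion * mu^2).
#' @param rng_seed Integer seed.
#' @return A list of class `function_dataset`: `$counts` ([rhizo_counts],
#'   KEGG x sample), `$tpm` (numeric matrix), `$truth` (tibble `kegg_id`,
#'   `class`, `target_community`), `$brite` (tibble `kegg_id`, `hierarchy`).
#' @export
generate_function_table <- function(n_per_class = 40L, n_replicates = 3L,
                                    base_mean = 200, fold_change = 16,
                                    dispersion = 0.2, rng_seed = 1L) {
  if (n_replicates < 3L) abort("`n_replicates` must be >= 3.")
  if (fold_change <= 0) abort("`fold_change` must be > 0.")
  communities <- c("rhizcom", "sbrb", "soil")
  classes <- c(paste0("enriched_", communities),
               paste0("suppressed_", communities), "balanced")
  with_sim_rng(rng_seed, 2L, function() {
    n_fun <- n_per_class * length(classes)
    ids <- sprintf("K%05d", seq_len(n_fun))
    class_of <- rep(classes, each = n_per_class)
    target <- ifelse(class_of == "balanced", NA_character_,
                     sub("^(enriched|suppressed)_", "", class_of))
    base <- rlnorm(n_fun, log(base_mean), 0.5)
    mu <- matrix(base, n_fun, 3, dimnames = list(ids, communities))
    for (i in seq_len(n_fun)) {
      if (startsWith(class_of[i], "enriched")) {
        mu[i, target[i]] <- mu[i, target[i]] * fold_change
      } else if (startsWith(class_of[i], "suppressed")) {
        mu[i, target[i]] <- mu[i, target[i]] / fold_change
      }
    }
    samples <- as.vector(outer(seq_len(n_replicates), communities,
                               function(r, cm) sprintf("%s_r%d", cm, r)))
    counts <- matrix(0L, n_fun, length(samples), dimnames = list(ids, samples))
    for (ci in seq_along(communities)) {
      for (r in seq_len(n_replicates)) {
        j <- (ci - 1L) * n_replicates + r
        counts[, j] <- rnbinom(n_fun, mu = mu[, ci], size = 1 / dispersion)
      }
    }
    tpm <- sweep(counts, 2, colSums(counts), "/") * 1e6
    hierarchies <- c("Carbohydrate metabolism", "Membrane transport",
                     "Energy metabolism", "Signal transduction",
                     "Transport and catabolism", "Xenobiotics biodegradation")
    brite <- tibble(kegg_id = ids,
                    hierarchy = sample(hierarchies, n_fun, replace = TRUE))
    meta <- tibble(sample_id = samples,
                   community = rep(communities, each = n_replicates),
                   cycle = NA_integer_,
                   replicate = rep(seq_len(n_replicates), times = 3))
    structure(list(counts = rhizo_counts(counts, meta), tpm = tpm,
                   truth = tibble(kegg_id = ids, class = class_of,
                                  target_community = target),
                   brite = brite,
                   expected_mu = mu),
              class = "function_dataset")
  })
}

#' Default reaction-set rules for pathway completeness
#'
#' Each rule is a named list with alternative `routes`, every route being a
#' set of KEGG reaction IDs that must all be present. The nicotinate and
#' riboflavin vitamin-biosynthesis routes and the lower-pathway reactions
#' follow the reaction IDs conventional for these pathways; the
#' upper-pathway disaccharide hydrolysis rules use representative hydrolase
#' reaction IDs and can be overridden by supplying custom rules.
#'
#' @return A named list of rules usable with [pathway_complete()].
#' @export
default_reaction_rules <- function() {
  list(
    nicotinate = list(name = "nicotinate",
                      routes = list("R07407",
                                    c("R00481", "R04292", "R03348", "R03346", "R02295"))),
    riboflavin = list(name = "riboflavin",
                      routes = list(c("R00425", "R03459", "R03458", "R07280", "R07281",
                                      "R04457", "R00066", "R00549", "R00161"))),
    sucrose_upper = list(name = "sucrose_upper", routes = list("R00801")),
    maltose_upper = list(name = "maltose_upper", routes = list("R01555")),
    cellobiose_upper = list(name = "cellobiose_upper", routes = list("R00026")),
    trehalose_upper = list(name = "trehalose_upper", routes = list("R00010")),
    glucose_lower = list(name = "glucose_lower", routes = list("R00299")),
    maltose_lower = list(name = "maltose_lower", routes = list("R00028")),
    fructose_lower = list(name = "fructose_lower", routes = list("R00760"))
  )
}

#' Generate a MAG table with planted community structure
#'
#' Draws MAG completeness/contamination spanning all quality tiers, assigns
#' per-community TPM percentages so that a configurable fraction of MAGs
#' violates the 1.5x single-community rule (and is hence multi-assigned),
#' plants the lower-pathway reactions in most MAGs, and plants complete
#' upper-disaccharide and vitamin (nicotinate, riboflavin) reaction routes
#' preferentially in seed-community (SbRB) and RhizCom MAGs.
#'
#' @param n_mags Named integer vector: MAGs per primary community.
#' @param frac_multi Fraction of MAGs whose TPM profile falls inside the
#'   1.5x band (multi-community).
#' @param p_vitamin Named list of per-community probabilities of a complete
#'   vitamin route; see defaults.
#' @param rng_seed Integer seed.
#' @return A list of class `mag_dataset`: `$mags` (tibble: `mag_id`,
#'   `completeness`, `contamination`, `strain_heterogeneity`, `taxonomy`,
#'   `tpm_rhizcom`, `tpm_sbrb`, `tpm_soil`, `reactions` list-column,
#'   `n_fructose_mannose`, `n_starch_sucrose`, `n_nicotinate`), `$truth`
#'   (tibble `mag_id`, `true_community`, `multi`).
#' @export
generate_mag_dataset <- function(n_mags = c(rhizcom = 20L, sbrb = 10L, soil = 15L),
                                 frac_multi = 0.2,
                                 p_vitamin = list(
                                   nicotinate = c(rhizcom = 0.35, sbrb = 0.6, soil = 0.3),
                                   riboflavin = c(rhizcom = 0.4, sbrb = 0.7, soil = 0.15),
                                   upper = c(rhizcom = 0.55, sbrb = 0.6, soil = 0.05)),
                                 rng_seed = 1L) {
  if (any(n_mags < 1L)) abort("Each community needs >= 1 MAG.")
  communities <- c("rhizcom", "sbrb", "soil")
  stopifnot(all(communities %in% names(n_mags)))
  rules <- default_reaction_rules()
  with_sim_rng(rng_seed, 3L, function() {
    n_total <- sum(n_mags)
    primary <- rep(communities, n_mags[communities])
    mag_id <- sprintf("MAG%03d", seq_len(n_total))
    # quality spans all tiers, most MAGs usable
    tier <- sample(c("high", "good", "medium", "low", "discarded"), n_total,
                   replace = TRUE, prob = c(0.3, 0.25, 0.25, 0.1, 0.1))
    completeness <- numeric(n_total)
    contamination <- numeric(n_total)
    for (i in seq_len(n_total)) {
      q <- switch(tier[i],
        high = c(runif(1, 90.5, 99.9), runif(1, 0, 4.9)),
        good = c(runif(1, 75.5, 90), runif(1, 0, 9.5)),
        medium = c(runif(1, 50.5, 75), runif(1, 0, 9.5)),
        low = c(runif(1, 10, 50), runif(1, 0, 9.5)),
        discarded = c(runif(1, 20, 99), runif(1, 10, 40)))
      completeness[i] <- q[1]; contamination[i] <- q[2]
    }
    multi <- runif(n_total) < frac_multi
    tpm <- matrix(0, n_total, 3, dimnames = list(mag_id, communities))
    for (i in seq_len(n_total)) {
      main <- runif(1, 30, 70)
      others <- setdiff(communities, primary[i])
      if (multi[i]) {
        partner <- sample(others, 1)
        tpm[i, primary[i]] <- main
        tpm[i, partner] <- main / runif(1, 1.01, 1.45)  # inside the 1.5x band
        tpm[i, setdiff(others, partner)] <- main / runif(1, 3, 10)
      } else {
        tpm[i, primary[i]] <- main
        tpm[i, others] <- main / runif(2, 2, 10)
      }
    }
    genera <- list(rhizcom = c("Variovorax", "Acidovorax", "Pseudomonas", "Flavobacterium"),
                   sbrb = c("Pantoea", "Paenibacillus", "Priestia", "Rhizobium"),
                   soil = c("Bacillus", "Streptomyces", "Sphingomonas", "Nitrospira"))
    taxonomy <- vapply(seq_len(n_total), function(i) {
      sprintf("%s sp. M%03d", sample(genera[[primary[i]]], 1), i)
    }, character(1))

    all_rxn <- unique(unlist(lapply(rules, function(r) unlist(r$routes))))
    lower_rxn <- c("R00299", "R00028", "R00760")
    upper_rules <- rules[c("sucrose_upper", "maltose_upper",
                           "cellobiose_upper", "trehalose_upper")]
    reactions <- vector("list", n_total)
    for (i in seq_len(n_total)) {
      rx <- lower_rxn[runif(3) < 0.9]
      for (vit in c("nicotinate", "riboflavin")) {
        p <- p_vitamin[[vit]][[primary[i]]]
        route <- rules[[vit]]$routes[[length(rules[[vit]]$routes)]]
        if (vit == "nicotinate" && runif(1) < 0.5) route <- rules[[vit]]$routes[[1]]
        if (runif(1) < p) {
          rx <- c(rx, route)
        } else if (runif(1) < 0.3) {
          rx <- c(rx, sample(route, max(0L, length(route) - sample(1:2, 1))))
        }
      }
      for (ur in upper_rules) {
        if (runif(1) < p_vitamin$upper[[primary[i]]]) rx <- c(rx, unlist(ur$routes))
      }
      reactions[[i]] <- sort(unique(rx))
    }
    lam <- function(base) ifelse(primary == "sbrb", base * 2.5, base)
    mags <- tibble(mag_id = mag_id, completeness = completeness,
                   contamination = contamination,
                   strain_heterogeneity = round(runif(n_total, 0, 30), 1),
                   taxonomy = taxonomy,
                   tpm_rhizcom = tpm[, "rhizcom"], tpm_sbrb = tpm[, "sbrb"],
                   tpm_soil = tpm[, "soil"], reactions = reactions,
                   n_fructose_mannose = rpois(n_total, lam(6)),
                   n_starch_sucrose = rpois(n_total, lam(7)),
                   n_nicotinate = rpois(n_total, lam(4)))
    structure(list(mags = mags,
                   truth = tibble(mag_id = mag_id, true_community = primary,
                                  multi = multi)),
              class = "mag_dataset")
  })
}

#' Generate a co-culture growth (c.f.u.) table with planted facilitation
#'
#' Emulates saccharide-utilization profiling: each focal strain is grown in
#' monoculture and in co-culture with a helper strain on a panel of carbon
#' sources plus a no-carbon control. Facilitation is planted on the
#' disaccharide sources: focal strains that cannot hydrolyse the
#' disaccharide grow poorly alone but gain a multiplicative boost in
#' co-culture with the helper.
#'
#' @param focal_strains Character vector of focal strain IDs.
#' @param helper Helper strain ID.
#' @param carbon_sources Saccharide panel (controls `none` always added).
#' @param facilitated_sources Sources on which facilitation is planted.
#' @param n_replicates Replicates per condition (default 3, as in triplicate
#'   profiling).
#' @param boost Multiplicative co-culture growth boost on facilitated
#'   sources.
#' @param rng_seed Integer seed.
#' @return A tibble (columns `strains`, `focal_strain`, `carbon_source`,
#'   `replicate`, `cfu`) with attribute `truth` (tibble of planted
#'   facilitation flags).
#' @export
generate_growth_table <- function(focal_strains = c("DGS2", "DGS4", "DGS16", "DGS31"),
                                  helper = "SbRB3",
                                  carbon_sources = c("glucose", "fructose", "sucrose",
                                                     "trehalose", "maltose", "cellobiose"),
                                  facilitated_sources = c("sucrose", "trehalose",
                                                          "maltose", "cellobiose"),
                                  n_replicates = 3L, boost = 8, rng_seed = 1L) {
  with_sim_rng(rng_seed, 4L, function() {
    rows <- list()
    truth <- list()
    baseline <- 5e4   # control (no carbon) background c.f.u.
    grow <- 2e6       # growth on a usable carbon source
    for (fs in focal_strains) {
      for (cs in c("none", carbon_sources)) {
        facil <- cs %in% facilitated_sources
        mono_mu <- if (cs == "none") baseline else if (facil) baseline * 1.5 else grow
        co_mu <- if (cs == "none") baseline else if (facil) mono_mu * boost else grow
        rows[[length(rows) + 1L]] <- tibble(
          strains = fs, focal_strain = fs, carbon_source = cs,
          replicate = seq_len(n_replicates),
          cfu = round(rlnorm(n_replicates, log(mono_mu), 0.15)))
        rows[[length(rows) + 1L]] <- tibble(
          strains = paste(fs, helper, sep = "+"), focal_strain = fs,
          carbon_source = cs, replicate = seq_len(n_replicates),
          cfu = round(rlnorm(n_replicates, log(co_mu), 0.15)))
        if (cs != "none") {
          truth[[length(truth) + 1L]] <- tibble(
            focal_strain = fs, carbon_source = cs, facilitated = facil)
        }
      }
    }
    out <- bind_rows(rows)
    attr(out, "truth") <- bind_rows(truth)
    out
  })
}

#' Write a complete synthetic dataset to disk
#'
#' Writes every artifact of the synthetic study in its plain-text exchange
#' format: count + metadata + taxonomy TSVs, ASV FASTA, Newick tree, origin
#' truth TSV, function count/TPM/truth TSVs, MAG TSV and growth TSV.
#'
#' @param dataset A [simulate_succession()] result.
#' @param functions A [generate_function_table()] result (optional).
#' @param mags A [generate_mag_dataset()] result (optional).
#' @param growth A [generate_growth_table()] result (optional).
#' @param dir Output directory.
#' @return Invisibly, the named vector of paths written.
#' @export
write_succession_dataset <- function(dataset, dir, functions = NULL,
                                     mags = NULL, growth = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- write_count_table(dataset$counts, dir, prefix = "asv")
  taxa <- dataset$pool$taxa
  paths[["fasta"]] <- file.path(dir, "asv_sequences.fasta")
  write_fasta(setNames(taxa$sequence, taxa$taxon_id), paths[["fasta"]])
  paths[["tree"]] <- file.path(dir, "asv_tree.nwk")
  write_newick(dataset$pool$tree, paths[["tree"]])
  paths[["origin"]] <- file.path(dir, "origin_truth.tsv")
  readr::write_tsv(dataset$origin, paths[["origin"]], progress = FALSE)
  if (!is.null(functions)) {
    p <- write_count_table(functions$counts, dir, prefix = "kegg")
    paths[c("kegg_counts", "kegg_metadata")] <- p[c("counts", "metadata")]
    paths[["kegg_tpm"]] <- write_matrix_tsv(functions$tpm,
                                            file.path(dir, "kegg_tpm.tsv"),
                                            id_col = "kegg_id")
    paths[["kegg_truth"]] <- file.path(dir, "kegg_truth.tsv")
    readr::write_tsv(functions$truth, paths[["kegg_truth"]], progress = FALSE)
    paths[["brite"]] <- file.path(dir, "kegg_brite.tsv")
    readr::write_tsv(functions$brite, paths[["brite"]], progress = FALSE)
  }
  if (!is.null(mags)) {
    paths[["mags"]] <- file.path(dir, "mag_table.tsv")
    write_mag_table(mags$mags, paths[["mags"]])
    paths[["mag_truth"]] <- file.path(dir, "mag_truth.tsv")
    readr::write_tsv(mags$truth, paths[["mag_truth"]], progress = FALSE)
  }
  if (!is.null(growth)) {
    paths[["growth"]] <- file.path(dir, "growth_table.tsv")
    write_growth_table(growth, paths[["growth"]])
  }
  invisible(paths)
}
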