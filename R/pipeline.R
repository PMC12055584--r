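#' Default pipeline configuration
#'
#' Gathers every stage threshold in one place, at the values conventional
#' for this analysis: prevalence filter 0.05, |log2FC| >= 2.5 and
#' padj < 0.01 for differential abundance, total-count filter 1000 for
#' metagenome functions, mean TPM > 0.5 for ternary inclusion, 1.5x TPM
#' ratio for MAG community assignment and 9999 permutations for
#' ANOSIM/PERMANOVA. Inputs default to `"simulate"`: the synthetic study is
#' generated from `rng_seed`.
#'
#' @param rng_seed Integer seed for every stochastic stage.
#' @param output_dir Report directory.
#' @param ... Overrides for any config entry.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(rng_seed = 1L, output_dir = "rhizotrace_report", ...) {
  cfg <- list(
    inputs = "simulate",
    simulation = succession_config(rng_seed = rng_seed),
    function_sim = list(n_per_class = 40L, n_replicates = 3L, base_mean = 200,
                        fold_change = 16, dispersion = 0.2),
    mag_sim = list(n_mags = c(rhizcom = 20L, sbrb = 10L, soil = 15L),
                   frac_multi = 0.2),
    prevalence_min = 0.05,
    excluded_lineages = c("Mitochondria", "Chloroplast"),
    css_quantile = "auto",
    lfc_min = 2.5,
    alpha = 0.01,
    min_total = 1000,
    min_mean_tpm = 0.5,
    assign_ratio = 1.5,
    n_perm = 9999,
    emergence_thresholds = c(1e-5, 1e-4, 1e-3),
    rng_seed = as.integer(rng_seed),
    output_dir = output_dir)
  dots <- list(...)
  for (nm in names(dots)) cfg[[nm]] <- dots[[nm]]
  structure(cfg, class = "pipeline_config")
}

#' Read or write a pipeline configuration as YAML
#'
#' @param path YAML path.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  sim <- raw$simulation %||% list()
  cfg <- do.call(pipeline_config,
                 c(list(rng_seed = raw$rng_seed %||% 1L,
                        output_dir = raw$output_dir %||% "rhizotrace_report"),
                   raw[setdiff(names(raw), c("rng_seed", "output_dir", "simulation"))]))
  if (length(sim) > 0) cfg$simulation <- do.call(succession_config, sim)
  cfg
}

#' @param config A [pipeline_config()].
#' @rdname read_pipeline_config
#' @export
write_pipeline_config <- function(config, path) {
  out <- unclass(config)
  out$simulation <- unclass(out$simulation)
  out$output_dir <- NULL  # runtime location, not an analysis parameter
  yaml::write_yaml(out, path)
  invisible(path)
}

stage_log <- function(stage, detail, t0) {
  inform(sprintf("[%s] %s (%.2fs)", stage, detail,
                 as.numeric(Sys.time()) - t0))
}

#' Run the full succession analysis pipeline
#'
#' Orchestrates the package end to end: simulate (or read) the study's
#' inputs, filter and CSS-normalize the ASV table, compute alpha/beta
#' diversity with ordination and clustering, trace RhizCom features to
#' their sources and compute emergence curves, run pairwise NB Wald
#' differential abundance on ASVs and KEGG functions, classify function
#' dominance, analyse MAGs, and test co-culture facilitation. Every result
#' is written as TSV (trees as Newick) into `config$output_dir`, with a run
#' manifest recording the package version, the configuration hash and the
#' seed. Stages whose inputs are absent are skipped with a log line. Reruns
#' with the same config and seed produce byte-identical directories.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a named list of the in-memory stage results.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(...) file.path(config$output_dir, ...)
  results <- list()
  t0 <- as.numeric(Sys.time())

  # --- inputs -------------------------------------------------------------
  if (identical(config$inputs, "simulate")) {
    pool <- generate_taxon_pool(config$simulation)
    dataset <- simulate_succession(pool, config$simulation)
    functions <- do.call(generate_function_table,
                         c(config$function_sim, list(rng_seed = config$rng_seed)))
    mags <- do.call(generate_mag_dataset,
                    c(config$mag_sim, list(rng_seed = config$rng_seed)))
    growth <- generate_growth_table(rng_seed = config$rng_seed)
    write_succession_dataset(dataset, out("inputs"), functions = functions,
                             mags = mags, growth = growth)
    stage_log("simulate", sprintf("%d taxa x %d samples", nrow(dataset$counts$counts),
                                  ncol(dataset$counts$counts)), t0)
  } else {
    p <- config$inputs
    dataset <- NULL
    if (!is.null(p$asv_counts)) {
      asv <- read_count_table(p$asv_counts, p$asv_metadata, p$asv_taxonomy)
      tree <- if (!is.null(p$tree)) read_newick(p$tree)
      seqs <- if (!is.null(p$fasta)) read_fasta(p$fasta)
      dataset <- list(counts = asv, pool = list(tree = tree, taxa = NULL),
                      origin = NULL)
      attr(dataset, "sequences") <- seqs
    }
    functions <- NULL
    mags <- if (!is.null(p$mag_table)) list(mags = read_mag_table(p$mag_table))
    growth <- if (!is.null(p$growth_table)) read_growth_table(p$growth_table)
    stage_log("load", "inputs read from disk", t0)
  }
  results$dataset <- dataset

  # --- ASV stages ---------------------------------------------------------
  if (!is.null(dataset)) {
    filtered <- filter_features(dataset$counts, config$prevalence_min,
                                config$excluded_lineages)
    write_count_table(filtered, out("filtered"), prefix = "asv_filtered")
    stage_log("filter", sprintf("%d -> %d features", nrow(dataset$counts$counts),
                                nrow(filtered$counts)), t0)

    css <- css_normalize(filtered, quantile = config$css_quantile)
    write_matrix_tsv(round(css$normalized, 6), out("css_normalized.tsv"))
    readr::write_tsv(css$scaling, out("css_factors.tsv"), progress = FALSE)
    stage_log("css", sprintf("quantile %.2f", css$quantile_used), t0)

    tree <- dataset$pool$tree
    alpha <- alpha_diversity(filtered, tree = tree)
    readr::write_tsv(alpha, out("alpha_diversity.tsv"), progress = FALSE)
    cyc <- alpha |> filter(!is.na(.data$cycle), .data$cycle > 0)
    trends <- cyc |>
      group_by(.data$metric) |>
      dplyr::group_modify(~ spearman_trend(.x$value, .x$cycle)) |>
      ungroup()
    readr::write_tsv(trends, out("alpha_trends.tsv"), progress = FALSE)

    bc <- bray_curtis_matrix(css)
    write_matrix_tsv(round(bc, 8), out("bray_curtis.tsv"), id_col = "sample_id")
    ord <- pcoa(bc)
    readr::write_tsv(left_join(ord$coordinates, filtered$metadata,
                               by = "sample_id") |>
                       mutate(across(dplyr::starts_with("PCo"), ~ round(.x, 8))),
                     out("pcoa_coordinates.tsv"), progress = FALSE)
    dendro <- hclust_complete(bc)
    write_newick(ape::as.phylo(dendro), out("dendrogram.nwk"))

    grp <- filtered$metadata$community
    results$anosim <- anosim_test(bc, grp, n_perm = config$n_perm,
                                  seed = config$rng_seed)
    results$permanova <- permanova_test(bc, grp, n_perm = config$n_perm,
                                        seed = config$rng_seed)
    readr::write_tsv(bind_rows(
      mutate(results$anosim, test = "anosim", statistic = .data$R,
             R = NULL),
      mutate(rename(results$permanova, statistic = "pseudo_F"),
             test = "permanova")),
      out("beta_group_tests.tsv"), progress = FALSE)
    stage_log("diversity", "alpha, beta, ordination, clustering", t0)

    # --- source tracing ---------------------------------------------------
    meta <- filtered$metadata
    final_cycle <- sprintf("cycle_%d", max(meta$cycle, na.rm = TRUE))
    pick <- function(cm) {
      css$normalized[, meta$sample_id[meta$community == cm], drop = FALSE]
    }
    seqs <- if (!is.null(dataset$pool$taxa)) {
      setNames(dataset$pool$taxa$sequence, dataset$pool$taxa$taxon_id)
    } else {
      attr(dataset, "sequences")
    }
    tracing <- classify_sources(pick(final_cycle), pick("soil_wash"),
                                pick("sbrb"), sequences = seqs)
    readr::write_tsv(tracing$assignments, out("source_assignments.tsv"),
                     progress = FALSE)
    readr::write_tsv(tracing$summary, out("source_summary.tsv"), progress = FALSE)
    readr::write_tsv(tracing$source_contribution, out("source_contribution.tsv"),
                     progress = FALSE)
    results$tracing <- tracing

    cycles <- c("soil_wash", sprintf("cycle_%d", sort(unique(
      meta$cycle[!is.na(meta$cycle) & meta$cycle > 0]))))
    cycle_tables <- lapply(cycles, pick)
    names(cycle_tables) <- cycles
    emergence <- emergence_curves(cycle_tables, config$emergence_thresholds)
    readr::write_tsv(emergence, out("emergence_curves.tsv"), progress = FALSE)
    results$emergence <- emergence
    stage_log("trace", sprintf("%d features traced", nrow(tracing$assignments)), t0)

    # --- ASV differential abundance ---------------------------------------
    da_pairs <- list(c(final_cycle, "soil_wash"), c(final_cycle, "sbrb"),
                     c("sbrb", "soil_wash"))
    results$asv_da <- list()
    for (pr in da_pairs) {
      sub <- subset_community(filtered, pr)
      da <- nb_wald(sub, sub$metadata$community, group_a = pr[1], group_b = pr[2],
                    lfc_min = config$lfc_min, alpha = config$alpha)
      nm <- paste(pr, collapse = "_vs_")
      readr::write_tsv(as_tibble(da), out(sprintf("da_asv_%s.tsv", nm)),
                       progress = FALSE)
      results$asv_da[[nm]] <- da
    }
    stage_log("da_asv", sprintf("%d pairwise comparisons", length(da_pairs)), t0)
  } else {
    stage_log("asv", "skipped: no ASV table", t0)
  }

  # --- function stages ----------------------------------------------------
  if (!is.null(functions)) {
    fc <- functions$counts
    pairs <- list(c("rhizcom", "sbrb"), c("rhizcom", "soil"), c("sbrb", "soil"))
    das <- lapply(pairs, function(pr) {
      sub <- subset_community(fc, pr)
      nb_wald(sub, sub$metadata$community, group_a = pr[1], group_b = pr[2],
              lfc_min = config$lfc_min, alpha = config$alpha,
              min_total = config$min_total)
    })
    names(das) <- vapply(pairs, paste, "", collapse = "_vs_")
    for (nm in names(das)) {
      readr::write_tsv(as_tibble(das[[nm]]), out(sprintf("da_kegg_%s.tsv", nm)),
                       progress = FALSE)
    }
    mean_tpm <- vapply(c("rhizcom", "sbrb", "soil"), function(cm) {
      rowMeans(functions$tpm[, fc$metadata$sample_id[fc$metadata$community == cm],
                             drop = FALSE])
    }, numeric(nrow(functions$tpm)))
    dom <- dominance_records(das[[1]], das[[2]], das[[3]],
                             cbind(kegg_id = rownames(functions$tpm),
                                   as.data.frame(mean_tpm)) |> as_tibble(),
                             min_mean_tpm = config$min_mean_tpm)
    readr::write_tsv(as_tibble(dom), out("dominance_records.tsv"), progress = FALSE)
    hf <- hierarchy_fractions(dom, functions$brite)
    readr::write_tsv(hf, out("hierarchy_fractions.tsv"), progress = FALSE)
    results$function_da <- das
    results$dominance <- dom
    stage_log("dominance", sprintf("%d functions classified", nrow(dom)), t0)
  } else {
    stage_log("functions", "skipped: no function table", t0)
  }

  # --- MAG stages -----------------------------------------------------------
  if (!is.null(mags)) {
    ann <- annotate_mags(mags$mags, ratio = config$assign_ratio)
    readr::write_tsv(select(ann, -"reactions", -"assigned"),
                     out("mag_annotations.tsv"), progress = FALSE)
    pc <- pathway_completeness_table(ann)
    readr::write_tsv(pc, out("mag_pathways.tsv"), progress = FALSE)
    usable <- filter(ann, .data$quality %in% c("high", "good", "medium"))
    comps <- list()
    for (cat in intersect(c("n_fructose_mannose", "n_starch_sucrose",
                            "n_nicotinate"), names(usable))) {
      cc <- try(category_comparison(usable, cat), silent = TRUE)
      if (!inherits(cc, "try-error")) comps[[cat]] <- tidy.category_comparison(cc)
    }
    if (length(comps) > 0) {
      readr::write_tsv(bind_rows(comps), out("mag_category_tests.tsv"),
                       progress = FALSE)
    }
    results$mags <- ann
    results$mag_pathways <- pc
    stage_log("mags", sprintf("%d MAGs (%d usable)", nrow(ann), nrow(usable)), t0)
  } else {
    stage_log("mags", "skipped: no MAG table", t0)
  }

  # --- growth stage ---------------------------------------------------------
  if (!is.null(growth)) {
    norm <- normalize_growth(growth)
    readr::write_tsv(norm, out("growth_normalized.tsv"), progress = FALSE)
    helper_rows <- grepl("\\+", norm$strains)
    tests <- norm |>
      filter(.data$carbon_source != "none") |>
      group_by(.data$focal_strain, .data$carbon_source) |>
      dplyr::group_modify(function(gd, key) {
        co <- gd$cfu_normalized[grepl("\\+", gd$strains)]
        mono <- gd$cfu_normalized[!grepl("\\+", gd$strains)]
        if (length(co) >= 3 && length(mono) >= 3) {
          facilitation_test(co, mono)
        } else {
          tibble(statistic = NA_real_, p = NA_real_, method = "insufficient_n",
                 alternative = "greater")
        }
      }) |>
      ungroup()
    tests$padj <- bh_adjust(tests$p)
    readr::write_tsv(tests, out("facilitation_tests.tsv"), progress = FALSE)
    results$growth <- tests
    stage_log("growth", sprintf("%d facilitation tests", nrow(tests)), t0)
  } else {
    stage_log("growth", "skipped: no growth table", t0)
  }

  # --- manifest -------------------------------------------------------------
  cfg_path <- out("config.yaml")
  write_pipeline_config(config, cfg_path)
  manifest <- tibble(
    key = c("package", "version", "rng_seed", "config_md5"),
    value = c("rhizotrace", as.character(utils::packageVersion("rhizotrace")),
              as.character(config$rng_seed),
              unname(tools::md5sum(cfg_path))))
  readr::write_tsv(manifest, out("manifest.tsv"), progress = FALSE)
  stage_log("done", sprintf("report in %s", config$output_dir), t0)
  invisible(results)
}

#' Run the synthetic demonstration study
#'
#' A desk-scale end-to-end run of the full pipeline on simulated data:
#' reduced sequencing depth and function-table size, all analysis
#' thresholds at their defaults. Deterministic given the seed.
#'
#' @param output_dir Report directory.
#' @param rng_seed Integer seed.
#' @return Invisibly, the pipeline results list.
#' @export
run_demo <- function(output_dir = "rhizotrace_demo", rng_seed = 1L) {
  cfg <- pipeline_config(
    rng_seed = rng_seed, output_dir = output_dir,
    function_sim = list(n_per_class = 20L, n_replicates = 3L, base_mean = 200,
                        fold_change = 16, dispersion = 0.2))
  cfg$simulation <- succession_config(rng_seed = rng_seed, seq_depth = 2e4L,
                                      depth_soil_wash = 2e4L)
  run_pipeline(cfg)
}
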