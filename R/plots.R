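#' Plot PCoA ordination
#'
#' @param object A [pcoa()] result.
#' @param metadata Optional sample metadata (joined on `sample_id`) with a
#'   `community` column used for colour.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.rhizo_pcoa <- function(object, metadata = NULL, ...) {
  df <- object$coordinates
  if (!is.null(metadata)) df <- left_join(df, as_tibble(metadata), by = "sample_id")
  lab <- function(i) sprintf("PCo%d (%.1f%%)", i, 100 * object$rel_eigen[i])
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$PCo1, y = .data$PCo2)) +
    ggplot2::labs(x = lab(1), y = lab(2)) +
    ggplot2::theme_minimal()
  if ("community" %in% names(df)) {
    p + ggplot2::geom_point(ggplot2::aes(colour = .data$community), size = 2)
  } else {
    p + ggplot2::geom_point(size = 2)
  }
}

#' Plot emergence curves
#'
#' Number of newly detected features per cycle, one line per
#' relative-abundance threshold.
#'
#' @param object An [emergence_curves()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.emergence_curves <- function(object, ...) {
  df <- mutate(as_tibble(object), threshold = factor(.data$threshold))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$cycle_index, y = .data$n_new,
                                   colour = .data$threshold)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "cycle (0 = inoculum)", y = "new features",
                  colour = "rel. abundance\nthreshold") +
    ggplot2::theme_minimal()
}

#' Volcano plot of an NB Wald result
#'
#' @param object An [nb_wald()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.nb_wald <- function(object, ...) {
  df <- as_tibble(object) |> filter(!is.na(.data$padj))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$log2fc,
                                   y = -log10(pmax(.data$padj, 1e-300)),
                                   colour = .data$significant)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_vline(xintercept = c(-1, 1) * attr(object, "lfc_min"),
                        linetype = "dashed") +
    ggplot2::geom_hline(yintercept = -log10(attr(object, "alpha")),
                        linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60", `TRUE` = "firebrick")) +
    ggplot2::labs(x = "log2 fold change", y = "-log10 adjusted p") +
    ggplot2::theme_minimal()
}

#' Ternary plot of dominance records
#'
#' Projects the three-community composition of each function onto the
#' two-simplex and colours by dominance category.
#'
#' @param object A [dominance_records()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.dominance_records <- function(object, ...) {
  df <- as_tibble(object) |> filter(.data$included)
  # barycentric -> cartesian
  df$x <- df$tern_sbrb + df$tern_soil / 2
  df$y <- df$tern_soil * sqrt(3) / 2
  tri <- data.frame(x = c(0, 1, 0.5, 0), y = c(0, 0, sqrt(3) / 2, 0))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_path(data = tri, colour = "grey40") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$category,
                                     size = log2(.data$mean_tpm + 1)),
                        alpha = 0.7) +
    ggplot2::scale_size_continuous(range = c(0.5, 3)) +
    ggplot2::annotate("text", x = c(-0.03, 1.03, 0.5), y = c(-0.03, -0.03, sqrt(3) / 2 + 0.04),
                      label = c("rhizcom", "sbrb", "soil"), size = 3) +
    ggplot2::coord_equal() +
    ggplot2::theme_void() +
    ggplot2::labs(colour = "dominance", size = "log2 mean TPM")
}

#' Boxplots of alpha diversity by community
#'
#' @param alpha An [alpha_diversity()] tibble.
#' @param metric Metric to plot (default `"shannon"`).
#' @return A ggplot.
#' @export
plot_alpha_diversity <- function(alpha, metric = "shannon") {
  df <- filter(as_tibble(alpha), .data$metric == !!metric)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$community, y = .data$value)) +
    ggplot2::geom_boxplot(outlier.size = 0.5) +
    ggplot2::geom_point(size = 0.8, alpha = 0.6) +
    ggplot2::labs(x = NULL, y = metric) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Bar chart of source-tracing label shares
#'
#' @param object A [classify_sources()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.source_assignment <- function(object, ...) {
  ggplot2::ggplot(object$summary,
                  ggplot2::aes(x = .data$label, y = .data$rel_abund)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = .data$n_features), vjust = -0.4,
                       size = 3) +
    ggplot2::labs(x = NULL, y = "share of sink relative abundance") +
    ggplot2::theme_minimal()
}
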