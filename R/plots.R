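# ggplot2 graphics for each result type. All plot functions return ggplot
# objects so callers can restyle them.

#' Plot sedimentation profiles as lines over the gradient
#' @param object A `sed_profile` tibble.
#' @param ... Unused.
#' @return A ggplot: abundance against fraction number, one line per entity.
#' @export
autoplot.sed_profile <- function(object, ...) {
  long <- as_tibble(object) |>
    tidyr::pivot_longer(-"entity_id", names_to = "fraction",
                        values_to = "abundance") |>
    mutate(fraction = as.integer(sub("^frac", "", .data$fraction)))
  ggplot2::ggplot(long, ggplot2::aes(.data$fraction, .data$abundance,
                                     group = .data$entity_id)) +
    ggplot2::geom_line(alpha = 0.5) +
    ggplot2::labs(x = "fraction (light → dense)",
                  y = if (is_normalized(object)) "relative abundance" else "abundance") +
    ggplot2::theme_minimal()
}

#' Heatmap of fraction-by-fraction correlations
#' @param cor_matrix Output of [fraction_correlation_matrix()].
#' @return A ggplot tile heatmap.
#' @export
plot_fraction_correlation <- function(cor_matrix) {
  d <- as_tibble(as.table(cor_matrix), .name_repair = "minimal")
  names(d) <- c("fraction_a", "fraction_b", "r")
  d$fraction_a <- as.integer(as.character(d$fraction_a))
  d$fraction_b <- as.integer(as.character(d$fraction_b))
  ggplot2::ggplot(d, ggplot2::aes(.data$fraction_a, .data$fraction_b,
                                  fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(min(d$r), 1)) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "fraction", y = "fraction", fill = "Pearson r") +
    ggplot2::theme_minimal()
}

#' Plot cluster mean profiles
#' @param object A `sed_clusters` object.
#' @param profiles The normalized `sed_profile` the clusters came from.
#' @param ... Unused.
#' @return A ggplot of mean relative abundance per cluster across fractions.
#' @export
autoplot.sed_clusters <- function(object, profiles, ...) {
  means <- cluster_mean_profiles(object, profiles)
  long <- means |>
    tidyr::pivot_longer(dplyr::starts_with("frac"), names_to = "fraction",
                        values_to = "mean_abundance") |>
    mutate(fraction = as.integer(sub("^frac", "", .data$fraction)),
           cluster = factor(.data$cluster))
  ggplot2::ggplot(long, ggplot2::aes(.data$fraction, .data$mean_abundance,
                                     colour = .data$cluster)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "fraction (light → dense)", y = "mean relative abundance",
                  colour = "cluster") +
    ggplot2::theme_minimal()
}

#' Histogram of RNA-protein co-sedimentation correlations
#' @param correlations Output of [rna_protein_correlations()].
#' @param binwidth Histogram bin width (default 0.1).
#' @return A ggplot histogram with the median marked.
#' @export
plot_correlation_histogram <- function(correlations, binwidth = 0.1) {
  d <- as_tibble(correlations)
  ggplot2::ggplot(d, ggplot2::aes(.data$r)) +
    ggplot2::geom_histogram(binwidth = binwidth, boundary = 0,
                            fill = "grey70", colour = "grey30") +
    ggplot2::geom_vline(xintercept = median(d$r), linetype = 2) +
    ggplot2::labs(x = "Pearson r (RNA vs encoded protein)", y = "genes") +
    ggplot2::theme_minimal()
}

#' Hexamer enrichment versus conservation scatter
#' @param object A `hexamer_stats` tibble; if it lacks a `conservation_rate`
#'   column, supply `conservation`.
#' @param conservation Optional [hexamer_conservation_rate()] tibble to join.
#' @param highlight Optional character vector of hexamers to emphasize.
#' @param ... Unused.
#' @return A ggplot scatter of `log2_ratio` against conservation rate.
#' @export
autoplot.hexamer_stats <- function(object, conservation = NULL,
                                   highlight = NULL, ...) {
  d <- as_tibble(object)
  if (!("conservation_rate" %in% names(d)) && !is.null(conservation)) {
    d <- left_join(d, as_tibble(conservation) |>
                     select("hexamer", "conservation_rate"),
                   by = "hexamer")
  }
  if (!("conservation_rate" %in% names(d))) {
    stop_cosedim("No conservation rates available; pass `conservation`.",
                 "cosedim_validation_error")
  }
  d$highlight <- d$hexamer %in% (highlight %||% character(0))
  ggplot2::ggplot(d, ggplot2::aes(.data$log2_ratio, .data$conservation_rate)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$highlight), alpha = 0.5,
                        show.legend = FALSE) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60", `TRUE` = "red")) +
    ggplot2::labs(x = "log2(foreground / background)", y = "conservation rate") +
    ggplot2::theme_minimal()
}

#' Cumulative conservation distributions by delta-PSI class
#' @param object A `psi_conservation` object.
#' @param ... Unused.
#' @return A ggplot of per-class empirical CDFs.
#' @export
autoplot.psi_conservation <- function(object, ...) {
  ggplot2::ggplot(object$ecdf, ggplot2::aes(.data$score, .data$ecdf,
                                            colour = .data$class)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "conservation score", y = "cumulative fraction",
                  colour = "class") +
    ggplot2::theme_minimal()
}

#' CLIP density distributions per correlation bin
#' @param object A `clip_bins` object.
#' @param ... Unused.
#' @return A ggplot of per-bin cumulative density distributions.
#' @export
autoplot.clip_bins <- function(object, ...) {
  ggplot2::ggplot(object$densities,
                  ggplot2::aes(.data$density, colour = .data$bin)) +
    ggplot2::stat_ecdf() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "CLIP sites per unit expression", y = "cumulative fraction",
                  colour = "correlation bin") +
    ggplot2::theme_minimal()
}
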