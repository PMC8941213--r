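# ggplot2 displays for each result type. Colour conventions follow the
# usual volcano/stacked-bar idioms of label-free proteomics reports.

#' Volcano plot of differential results
#'
#' Red: significant (the p/q conjunction) with |log2FC| > 1; green:
#' non-significant but |log2FC| > 1; grey: the rest. Fold change is a
#' display attribute only and never gates significance.
#'
#' @param results Output of [call_significant()].
#' @param p_max Reference line for the p threshold (default 0.005).
#' @return A ggplot object.
#' @export
plot_volcano <- function(results, p_max = 0.005) {
  results <- results |>
    filter(!is.na(.data$p_value)) |>
    mutate(status = dplyr::case_when(
      .data$significant & .data$high_fold_change ~ "significant, FC > 2",
      .data$significant ~ "significant",
      .data$high_fold_change ~ "FC > 2",
      TRUE ~ "n.s."
    ))
  ggplot2::ggplot(results,
                  ggplot2::aes(.data$log2_fc, -log10(.data$p_value),
                               colour = .data$status)) +
    ggplot2::geom_point(alpha = 0.7, size = 1.2) +
    ggplot2::geom_hline(yintercept = -log10(p_max), linetype = "dashed",
                        linewidth = 0.3) +
    ggplot2::geom_vline(xintercept = c(-1, 1), linetype = "dotted",
                        linewidth = 0.3) +
    ggplot2::scale_colour_manual(values = c(
      "significant, FC > 2" = "red3", "significant" = "orange",
      "FC > 2" = "forestgreen", "n.s." = "grey60")) +
    ggplot2::labs(x = "log2 fold change (UC - healthy)",
                  y = "-log10 p", colour = NULL) +
    ggplot2::theme_minimal()
}

#' @method autoplot moderated_fit
#' @export
autoplot.moderated_fit <- function(object, ...) {
  plot_volcano(call_significant(tidy(object)), ...)
}

#' PCA score plot
#' @param scores Output of [pca_scores()].
#' @return A ggplot object.
#' @export
plot_pca <- function(scores) {
  ve <- attr(scores, "var_explained")
  lab <- function(i) {
    if (is.null(ve)) paste0("PC", i)
    else sprintf("PC%d (%.1f%%)", i, 100 * ve[i])
  }
  ggplot2::ggplot(scores, ggplot2::aes(.data$pc1, .data$pc2,
                                       colour = .data$cohort)) +
    ggplot2::geom_point(size = 2.5) +
    ggplot2::scale_colour_manual(values = c(healthy = "red3", uc = "blue3")) +
    ggplot2::labs(x = lab(1), y = lab(2)) +
    ggplot2::theme_minimal()
}

#' Heatmap of the Euclidean sample-distance matrix
#' @param dmat Matrix from [sample_distance_matrix()].
#' @return A ggplot object.
#' @export
plot_sample_distances <- function(dmat) {
  long <- as_tibble(as.table(dmat), .name_repair = "minimal")
  names(long) <- c("sample_a", "sample_b", "distance")
  ggplot2::ggplot(long, ggplot2::aes(.data$sample_a, .data$sample_b,
                                     fill = .data$distance)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradientn(colours = c("navy", "white", "orangered")) +
    ggplot2::labs(x = NULL, y = NULL, fill = "Euclidean\ndistance") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Stacked GO relative-abundance bars
#' @param abundance A GO abundance tibble (either mode).
#' @param namespace Namespace to display (default the first present).
#' @return A ggplot object.
#' @export
plot_go_abundance <- function(abundance, namespace = NULL) {
  ns <- namespace %||% abundance$namespace[1]
  dat <- abundance |> filter(.data$namespace == ns)
  ggplot2::ggplot(dat, ggplot2::aes(.data$sample, .data$share,
                                    fill = .data$go_id)) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::labs(x = NULL, y = "share", fill = "GO term",
                  title = paste(unique(dat$mode), ns)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Stacked taxonomy profile bars
#' @param profile Output of [peptide_taxon_profile()] or
#'   [amplicon_profile()].
#' @return A ggplot object.
#' @export
plot_taxon_profile <- function(profile) {
  ggplot2::ggplot(profile, ggplot2::aes(.data$sample, .data$share,
                                        fill = .data$taxon)) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::labs(x = NULL, y = "share", fill = NULL,
                  subtitle = unique(profile$basis)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Stacked Novor-score histogram (assigned vs unassigned)
#' @param object A `score_histograms` object.
#' @param cutoff Reference line at the dark-peptidome cutoff (default 75).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot score_histograms
#' @export
autoplot.score_histograms <- function(object, cutoff = 75, ...) {
  long <- object$histogram |>
    tidyr::pivot_longer(c("assigned", "unassigned"),
                        names_to = "status", values_to = "count")
  ggplot2::ggplot(long, ggplot2::aes(.data$bin, .data$count,
                                     fill = .data$status)) +
    ggplot2::geom_col(position = "stack", width = 1) +
    ggplot2::geom_vline(xintercept = cutoff, colour = "red",
                        linetype = "dashed") +
    ggplot2::scale_fill_manual(values = c(assigned = "darkgreen",
                                          unassigned = "palegreen3")) +
    ggplot2::facet_wrap(ggplot2::vars(.data$sample)) +
    ggplot2::labs(x = "Novor score", y = "MS2 spectra", fill = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
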