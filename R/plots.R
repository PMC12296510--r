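#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_tile geom_col
#'   geom_histogram geom_vline geom_hline facet_wrap labs theme_minimal
#'   scale_fill_gradient2 scale_fill_viridis_c
NULL

#' Volcano plot of a differential result
#'
#' @param results A [phospho_difftest()] tibble.
#' @param q_threshold Highlighting threshold (default 0.05).
#' @return A ggplot object.
#' @export
plot_volcano <- function(results, q_threshold = 0.05) {
  d <- dplyr::filter(results, !is.na(.data$p_value))
  d$significant <- !is.na(d$q_value) & d$q_value < q_threshold
  ggplot(d, aes(x = .data$log2fc, y = -log10(.data$p_value),
                colour = .data$significant)) +
    geom_point(size = 0.6, alpha = 0.6) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "#2166ac")) +
    geom_vline(xintercept = 0, linetype = "dotted") +
    labs(x = "log2 fold change", y = "-log10 p",
         colour = paste0("q < ", q_threshold),
         title = unique(d$contrast)[1]) +
    theme_minimal()
}

#' @method autoplot ppm
#' @export
autoplot.ppm <- function(object, ...) {
  d <- generics::tidy(object)
  ggplot(d, aes(x = .data$position, y = .data$aa, fill = .data$frequency)) +
    geom_tile() +
    scale_fill_viridis_c(na.value = "grey90") +
    labs(x = "Position relative to phosphosite", y = NULL,
         fill = "Frequency") +
    theme_minimal()
}

#' @method autoplot preference_matrix
#' @export
autoplot.preference_matrix <- function(object, ...) {
  d <- generics::tidy(object)
  ggplot(d, aes(x = .data$position, y = .data$aa, fill = .data$log2_ratio)) +
    geom_tile() +
    scale_fill_gradient2(low = "#2166ac", mid = "white", high = "#b2182b",
                         na.value = "grey85") +
    labs(x = "Position relative to phosphosite", y = NULL,
         fill = "log2 sens/insens") +
    theme_minimal()
}

#' Spacer histograms of classified SLiM hits
#'
#' @param hits Classified hits from [classify_hits()].
#' @param by Faceting column (default `"motif"`).
#' @return A ggplot object.
#' @export
plot_spacer_distribution <- function(hits, by = "motif") {
  d <- dplyr::filter(hits,
                     .data$spacer_class %in% c("upstream", "downstream"))
  ggplot(d, aes(x = .data$spacer, fill = .data$spacer_class)) +
    geom_histogram(binwidth = 2, position = "identity", alpha = 0.7) +
    facet_wrap(by, scales = "free_y") +
    labs(x = "Spacer (residues)", y = "Hits", fill = NULL) +
    theme_minimal()
}

#' Bar chart of Venn region counts
#'
#' @param object A `target_overlap` from [intersect_calls()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot target_overlap
#' @export
autoplot.target_overlap <- function(object, ...) {
  ggplot(object$venn, aes(x = stats::reorder(.data$region, -.data$count),
                          y = .data$count)) +
    geom_col(fill = "#2166ac") +
    labs(x = NULL, y = "Sites") +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30,
                                                       hjust = 1))
}
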