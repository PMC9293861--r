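# ggplot2 visualisations for the main result types.

#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_line geom_hline
#'   geom_vline geom_histogram geom_tile labs theme_minimal scale_fill_gradient2
#' @export
ggplot2::autoplot

#' Hockey-stick plot of a super-enhancer call
#'
#' Scaled ranked-signal curve with the tangent cutoff; super-enhancers
#' highlighted.
#'
#' @param object A `tlr_secall`.
#' @param ... Unused.
#' @method autoplot tlr_secall
#' @export
autoplot.tlr_secall <- function(object, ...) {
  df <- tidy(object)
  p <- ggplot(df, aes(x = .data$scaled_rank, y = .data$scaled_signal,
                      colour = .data$is_super)) +
    geom_point(size = 0.8) +
    labs(x = "scaled rank", y = "scaled signal", colour = "super-enhancer") +
    theme_minimal()
  if (!is.na(attr(object, "cutoff_index"))) {
    p <- p + geom_vline(xintercept = df$scaled_rank[attr(object, "cutoff_index")],
                        linetype = "dashed")
  }
  p
}

#' Ratio distribution of a synergy result
#'
#' Histogram of the combined/(CpG + pIC) ratio with the synergy and
#' antagonism thresholds marked.
#'
#' @param object A `tlr_synergy`.
#' @param bins Histogram bins.
#' @param ... Unused.
#' @method autoplot tlr_synergy
#' @export
autoplot.tlr_synergy <- function(object, bins = 50, ...) {
  df <- dplyr::filter(tidy(object), !is.na(.data$ratio))
  ggplot(df, aes(x = .data$ratio)) +
    geom_histogram(bins = bins) +
    geom_vline(xintercept = attr(object, "upper"), linetype = "dashed") +
    geom_vline(xintercept = attr(object, "lower"), linetype = "dashed") +
    labs(x = "combined / (CpG + pIC) ratio", y = "genes") +
    theme_minimal()
}

#' Log odds-ratio heatmap of set associations
#'
#' @param association Output of [fisher_overlap_matrix()].
#' @param cap Absolute cap for plotted log odds (keeps infinities drawable).
#' @export
plot_association_heatmap <- function(association, cap = 5) {
  df <- dplyr::mutate(association,
                      log_odds_capped = pmax(pmin(.data$log_odds, cap), -cap))
  ggplot(df, aes(x = .data$set_b, y = .data$set_a, fill = .data$log_odds_capped)) +
    geom_tile() +
    scale_fill_gradient2(low = "blue", mid = "white", high = "red", midpoint = 0) +
    labs(x = NULL, y = NULL, fill = "log OR") +
    theme_minimal()
}

#' Mean per-condition profiles of peak clusters
#'
#' @param clusters A `tlr_clusters` with `label` (or `cluster`) per peak.
#' @param fp The matching `fc_pattern` of per-condition means.
#' @export
plot_cluster_profiles <- function(clusters, fp) {
  lab <- if ("label" %in% names(clusters)) clusters$label else clusters$cluster
  df <- tibble::as_tibble(unclass(fp)) %>%
    dplyr::inner_join(tibble::tibble(feature_id = clusters$peak_id, label = lab),
                      by = "feature_id") %>%
    tidyr::pivot_longer(-c("feature_id", "label"),
                        names_to = "condition", values_to = "mean_norm") %>%
    dplyr::group_by(.data$label, .data$condition) %>%
    dplyr::summarise(mean_norm = mean(.data$mean_norm), .groups = "drop") %>%
    dplyr::mutate(condition = factor(.data$condition, levels = unique(.data$condition)))
  ggplot(df, aes(x = .data$condition, y = .data$mean_norm,
                 group = .data$label, colour = .data$label)) +
    geom_line() + geom_point() +
    labs(x = NULL, y = "mean normalized signal", colour = "cluster") +
    theme_minimal()
}
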