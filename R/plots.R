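#' Plot a Kaplan-Meier curve
#'
#' Step plot of the product-limit estimate, with censoring ticks.
#'
#' @param object A `km_estimate`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot km_estimate
#' @export
autoplot.km_estimate <- function(object, ...) {
  df <- tidy(object)
  df0 <- dplyr::bind_rows(tibble::tibble(time = 0, n_risk = object$n,
                                         n_event = 0L, n_censor = 0L, surv = 1), df)
  cens <- df[df$n_censor > 0, ]
  ggplot2::ggplot(df0, ggplot2::aes(x = .data$time, y = .data$surv)) +
    ggplot2::geom_step() +
    ggplot2::geom_point(data = cens, shape = 3, size = 2) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Time (days)", y = "Survival probability") +
    ggplot2::theme_minimal()
}

#' Plot module sizes of a partition
#'
#' @param object A `module_partition`.
#' @param ... Unused.
#' @return A ggplot bar chart of module sizes.
#' @method autoplot module_partition
#' @export
autoplot.module_partition <- function(object, ...) {
  df <- tibble::tibble(module = factor(names(object$modules),
                                       levels = names(object$modules)),
                       size = lengths(object$modules))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$module, y = .data$size)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "Module", y = "Genes",
                  title = paste0(object$cohort_id, " (",
                                 length(object$unassigned), " unassigned)")) +
    ggplot2::theme_minimal()
}

#' Heatmap of cross-cohort module conservation
#'
#' Jaccard index per module pair for one cohort pair, significance marked
#' with an asterisk.
#'
#' @param conservation A `module_conservation` tibble.
#' @param cohort_a,cohort_b Cohort ids to display (default: the first pair
#'   present).
#' @return A ggplot tile plot.
#' @export
plot_conservation <- function(conservation, cohort_a = NULL, cohort_b = NULL) {
  cohort_a <- cohort_a %||% conservation$cohort_a[1]
  cohort_b <- cohort_b %||% conservation$cohort_b[1]
  df <- conservation[conservation$cohort_a == cohort_a &
                     conservation$cohort_b == cohort_b, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$module_a, y = .data$module_b,
                                   fill = .data$jaccard)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = ifelse(.data$significant, "*", "")),
                       colour = "white", size = 6) +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(x = paste(cohort_a, "modules"), y = paste(cohort_b, "modules"),
                  fill = "Jaccard") +
    ggplot2::theme_minimal()
}

#' Dot plot of top enrichment results
#'
#' @param result An `enrichment_result`.
#' @param k Number of top sets to show.
#' @return A ggplot dot plot (-log10 q-value vs set, dot size = overlap).
#' @export
plot_enrichment <- function(result, k = 20) {
  df <- utils::head(result, k)
  df$set_id <- factor(df$set_id, levels = rev(df$set_id))
  ggplot2::ggplot(df, ggplot2::aes(x = -log10(.data$q_value), y = .data$set_id,
                                   size = .data$overlap_count,
                                   colour = .data$enriched)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = expression(-log[10]~"q-value"), y = NULL,
                  size = "Overlap", colour = "Enriched") +
    ggplot2::theme_minimal()
}

#' Bar plot of top reporter features
#'
#' @param scores A reporter-score tibble from [reporter_scores()].
#' @param k Number of top features to show.
#' @return A ggplot bar chart of corrected Z-scores.
#' @export
plot_reporter <- function(scores, k = 20) {
  df <- utils::head(scores, k)
  df$feature_id <- factor(df$feature_id, levels = rev(df$feature_id))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$z_corrected, y = .data$feature_id)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "Corrected reporter Z", y = NULL) +
    ggplot2::theme_minimal()
}
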