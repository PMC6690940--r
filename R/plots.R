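#' Category counts per variant
#'
#' Bar chart of the number of islands per endemism category, one bar group
#' per index variant.
#'
#' @param object An `endemism_result` from [run_endemism()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.endemism_result <- function(object, ...) {
  d <- object$summary |>
    dplyr::filter(!.data$category %in% c("significant", "not_significant"))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$category, y = .data$count,
                                  fill = .data$variant)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "endemism category", y = "islands",
                  fill = "variant") +
    ggplot2::theme_minimal()
}

#' PE against PEalt, colored by category
#'
#' Each point is an island; the diagonal marks RPE = 1, above it rare long
#' branches dominate (paleo side), below it rare short branches (neo side).
#'
#' @param result An `endemism_result`.
#' @param variant Which variant to plot (default `"expanded"`).
#' @return A ggplot object.
#' @export
plot_pe_scatter <- function(result, variant = "expanded") {
  d <- tidy(result) |> dplyr::filter(.data$variant == !!variant)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$pe_alt, y = .data$pe,
                                  color = .data$category)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         color = "grey50") +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(x = "PEalt (uniform branch lengths, My)", y = "PE (My)",
                  color = "category", title = paste0(variant, " variant")) +
    ggplot2::theme_minimal()
}

#' Null distribution of a metric for one island
#'
#' Requires an ensemble built with `keep_samples = TRUE`.
#'
#' @param object A `null_ensemble` from [null_metric_distribution()].
#' @param island Island id to plot.
#' @param metric One of `"pe"`, `"pe_alt"`, `"rpe"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.null_ensemble <- function(object, island, metric = "pe", ...) {
  if (is.null(object$samples)) {
    abort("ensemble was built without keep_samples = TRUE",
          class = "islandpe_config_error")
  }
  metric <- match.arg(metric, c("pe", "pe_alt", "rpe"))
  i <- match(island, object$scores$island_id)
  if (is.na(i)) abort(paste0("unknown island: ", island),
                      class = "islandpe_data_error")
  d <- tibble::tibble(value = object$samples[i, metric, ])
  obs <- object$scores[[metric]][i]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey70") +
    ggplot2::geom_vline(xintercept = obs, color = "red") +
    ggplot2::labs(x = metric, y = "simulations",
                  title = sprintf("%s: observed vs null (%s)", island, metric)) +
    ggplot2::theme_minimal()
}
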