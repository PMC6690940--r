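#' Tidy an endemism result into one row per island and variant
#'
#' @param x An `endemism_result` from [run_endemism()].
#' @param ... Unused.
#' @return Tibble joining scores, tail frequencies and category per
#'   (`island_id`, `variant`).
#' @exportS3Method generics::tidy
tidy.endemism_result <- function(x, ...) {
  x$scores |>
    dplyr::inner_join(dplyr::select(x$frequencies, -"n_sims"),
                      by = c("island_id", "variant")) |>
    dplyr::inner_join(dplyr::select(x$assignments, "island_id", "variant",
                                    "category"),
                      by = c("island_id", "variant")) |>
    dplyr::arrange(.data$island_id, .data$variant)
}

#' One-row summary of an endemism result
#'
#' @param x An `endemism_result`.
#' @param ... Unused.
#' @return One-row tibble: islands analyzed, simulations, levels, and the
#'   number of significant islands per variant run.
#' @exportS3Method generics::glance
glance.endemism_result <- function(x, ...) {
  sig <- x$summary |>
    dplyr::filter(.data$category == "significant") |>
    dplyr::select("variant", "count") |>
    tidyr::pivot_wider(names_from = "variant", values_from = "count",
                       names_prefix = "n_significant_")
  dplyr::bind_cols(
    tibble::tibble(n_islands = x$config$total_islands,
                   n_sims = x$config$n_sims,
                   alpha = x$config$alpha,
                   super_alpha = x$config$super_alpha),
    sig
  )
}

#' Tidy the species-area richness model coefficients
#'
#' @param x A `richness_model` from [fit_richness_model()].
#' @param ... Unused.
#' @return Tibble with `term`, `estimate`, `std.error`, `statistic`,
#'   `p.value`. The `log10(area)` estimate is the species-area exponent.
#' @exportS3Method generics::tidy
tidy.richness_model <- function(x, ...) {
  cf <- summary(x$fit)$coefficients
  tibble::tibble(term = rownames(cf), estimate = unname(cf[, 1]),
                 std.error = unname(cf[, 2]), statistic = unname(cf[, 3]),
                 p.value = unname(cf[, 4]))
}

#' One-row summary of a richness model fit
#'
#' @param x A `richness_model`.
#' @param ... Unused.
#' @return One-row tibble with `r.squared`, `sigma`, `nobs`, `unreliable`.
#' @exportS3Method generics::glance
glance.richness_model <- function(x, ...) {
  s <- summary(x$fit)
  tibble::tibble(r.squared = s$r.squared, sigma = s$sigma,
                 nobs = x$n, unreliable = x$unreliable)
}
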