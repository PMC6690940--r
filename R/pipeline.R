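#' Run the full endemism analysis
#'
#' End-to-end orchestration for one or both index variants: per-island
#' PE/PEalt/RPE, fixed-marginal null test, tail frequencies, category
#' assignment, per-category summary, and (when both variants run) the
#' category-change comparison. Under the restricted variant the null model
#' still randomizes across all islands, but islands harboring no
#' island-specific genus are excluded from testing and categorization so
#' they cannot be falsely identified as areas of restricted endemism.
#'
#' @param tree Dated genus phylogeny ([ape::phylo]).
#' @param incidence Binary islands x genera matrix (see [build_incidence()]).
#' @param annotations Tibble with `genus`, `continental` (needed for the
#'   restricted variant).
#' @param variants Subset of `c("expanded", "restricted")`.
#' @param alpha,super_alpha Significance levels (defaults 0.05 and 0.01).
#' @param n_sims Null randomizations per variant (default 1000).
#' @param seed Integer seed; per-variant seeds are derived from it.
#' @param n_max Restricted-variant denominator for continental branches;
#'   default number of islands.
#' @param l_uniform Uniform branch length for PEalt; default mean branch
#'   length.
#' @param burn_in,thinning Randomizer chain controls.
#' @param coverage Optional tibble `island_id`, `icer` from [ice_coverage()].
#' @param icer_mode How the coverage score corrects the metrics: `"off"`
#'   (default), `"divide_observed"` (observed metrics divided by ICEr before
#'   tail counting) or `"divide_both"` (observed and null divided alike — a
#'   per-island multiplier on both sides leaves the rank-based tail
#'   frequencies, and hence the categories, unchanged).
#' @return Object of class `endemism_result`: tibbles `scores`,
#'   `frequencies`, `assignments`, `summary`, `comparison` (or `NULL`),
#'   `restricted_islands`, and the `config`.
#' @export
run_endemism <- function(tree, incidence, annotations = NULL,
                         variants = c("expanded", "restricted"),
                         alpha = 0.05, super_alpha = 0.01,
                         n_sims = 1000, seed = NULL,
                         n_max = NULL, l_uniform = NULL,
                         burn_in = NULL, thinning = NULL,
                         coverage = NULL,
                         icer_mode = c("off", "divide_observed", "divide_both")) {
  variants <- match.arg(variants, several.ok = TRUE)
  icer_mode <- match.arg(icer_mode)
  validate_incidence(incidence)
  total_islands <- nrow(incidence)
  icer <- NULL
  if (!is.null(coverage)) {
    icer <- setNames(coverage$icer, coverage$island_id)[rownames(incidence)]
    icer[is.na(icer)] <- 1
  }
  obs_scale <- if (icer_mode == "divide_observed" && !is.null(icer)) 1 / icer else NULL

  scores <- list(); freqs <- list(); assigns <- list(); summaries <- list()
  restricted_ids <- NULL
  for (v in variants) {
    vseed <- if (is.null(seed)) NULL else
      (as.integer(seed) + match(v, c("expanded", "restricted"))) %% 2000000011L
    ens <- null_metric_distribution(
      tree, incidence, annotations = annotations, variant = v,
      n_sims = n_sims, seed = vseed, n_max = n_max, l_uniform = l_uniform,
      burn_in = burn_in, thinning = thinning, obs_scale = obs_scale
    )
    sc <- ens$scores
    fr <- tail_frequencies(ens)
    if (v == "restricted") {
      if (is.null(annotations)) {
        abort("restricted variant needs `annotations`",
              class = "islandpe_config_error")
      }
      restricted_ids <- restrict_islands(incidence, annotations)
      if (!length(restricted_ids)) {
        inform("restricted variant: no eligible islands (all genera continental)")
      }
      sc <- dplyr::filter(sc, .data$island_id %in% restricted_ids)
      fr <- dplyr::filter(fr, .data$island_id %in% restricted_ids)
    }
    if (icer_mode != "off" && !is.null(icer)) {
      div <- unname(icer[sc$island_id])
      sc <- dplyr::mutate(sc, pe = .data$pe / div, pe_alt = .data$pe_alt / div,
                          rpe = .data$rpe / div)
    }
    asg <- assign_categories(fr, alpha = alpha, super_alpha = super_alpha)
    scores[[v]] <- sc
    freqs[[v]] <- fr
    assigns[[v]] <- asg
    summaries[[v]] <- dplyr::mutate(
      summarize_categories(asg, total_islands), variant = v, .before = 1)
  }
  comparison <- if (all(c("expanded", "restricted") %in% variants)) {
    compare_variants(assigns$expanded, assigns$restricted)
  } else NULL
  structure(
    list(
      scores = dplyr::bind_rows(scores),
      frequencies = dplyr::bind_rows(freqs),
      assignments = dplyr::bind_rows(assigns),
      summary = dplyr::bind_rows(summaries),
      comparison = comparison,
      restricted_islands = restricted_ids,
      config = list(variants = variants, alpha = alpha,
                    super_alpha = super_alpha, n_sims = n_sims, seed = seed,
                    n_max = n_max %||% total_islands,
                    total_islands = total_islands, icer_mode = icer_mode)
    ),
    class = "endemism_result"
  )
}

#' @export
print.endemism_result <- function(x, ...) {
  cat(sprintf("<endemism_result> %d islands, variants: %s, n_sims = %d\n",
              x$config$total_islands,
              paste(x$config$variants, collapse = "+"), x$config$n_sims))
  sig <- dplyr::filter(x$summary, .data$category == "significant")
  for (i in seq_len(nrow(sig))) {
    cat(sprintf("  %s: %d significant islands (%.3g%%)\n",
                sig$variant[i], sig$count[i], sig$percent[i]))
  }
  invisible(x)
}

#' Persist an endemism result to disk
#'
#' Writes the per-island results table for each variant (TSV, see
#' [write_results()]), the category summary, the variant comparison when
#' present, and a JSON run-metadata sidecar (seed, parameters, counts).
#'
#' @param result An `endemism_result`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_endemism_results <- function(result, dir) {
  stopifnot(inherits(result, "endemism_result"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_results(result$scores, result$frequencies, result$assignments,
                file.path(dir, "island_results.tsv"))
  readr::write_tsv(result$summary, file.path(dir, "category_summary.tsv"))
  if (!is.null(result$comparison)) {
    readr::write_tsv(result$comparison, file.path(dir, "category_changes.tsv"))
  }
  meta <- c(result$config,
            list(n_assigned = nrow(result$assignments),
                 written = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")))
  jsonlite::write_json(meta, file.path(dir, "run_metadata.json"),
                       auto_unbox = TRUE, null = "null")
  invisible(dir)
}

#' Coverage-threshold sensitivity sweep
#'
#' Re-runs the categorization on nested island subsets obtained by gradually
#' excluding islands whose geographic-coverage score (ICEr) falls below each
#' threshold, and reports whether every island's category is stable across
#' all subsets in which it appears. Threshold 0 reproduces the base run.
#'
#' @inheritParams run_endemism
#' @param coverage Tibble `island_id`, `icer` (see [ice_coverage()]).
#' @param thresholds Numeric vector of ICEr cutoffs (islands with
#'   `icer >= t` are kept at threshold `t`).
#' @param variant Single variant for the sweep (default `"expanded"`).
#' @param ... Passed to [run_endemism()].
#' @return Tibble with one row per island x threshold (`island_id`,
#'   `threshold`, `category`) plus a `stability` attribute: per-island flag,
#'   `TRUE` when the category is identical across all thresholds where the
#'   island was analyzed.
#' @export
sensitivity_sweep <- function(tree, incidence, coverage, thresholds,
                              annotations = NULL, variant = "expanded", ...) {
  validate_incidence(incidence)
  icer <- setNames(coverage$icer, coverage$island_id)[rownames(incidence)]
  icer[is.na(icer)] <- 1
  rows <- list()
  for (t in sort(thresholds)) {
    keep <- rownames(incidence)[icer >= t]
    if (!length(keep)) {
      warn(sprintf("threshold %.3g excludes all islands; skipped", t))
      next
    }
    sub <- incidence[keep, , drop = FALSE]
    sub <- sub[, colSums(sub) > 0, drop = FALSE]
    res <- run_endemism(tree, sub, annotations = annotations,
                        variants = variant, ...)
    rows[[as.character(t)]] <- dplyr::transmute(
      res$assignments, .data$island_id, threshold = t,
      category = as.character(.data$category))
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble::tibble(island_id = character(), threshold = numeric(),
                          category = character())
  }
  stability <- out |>
    dplyr::group_by(.data$island_id) |>
    dplyr::summarise(stable = dplyr::n_distinct(.data$category) == 1,
                     n_thresholds = dplyr::n())
  attr(out, "stability") <- stability
  out
}
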