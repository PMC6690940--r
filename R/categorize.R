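#' Endemism category labels
#' @keywords internal
ENDEMISM_CATEGORIES <- c("not_significant", "significant_other",
                         "neo", "paleo", "mixed", "super")

#' Assign endemism categories from tail frequencies
#'
#' Two-tailed test at level `alpha`: an island is a significant area of
#' phylogenetic endemism when the observed PE (the RPE numerator) or PEalt
#' (the denominator) exceeds a fraction `1 - alpha` of the null values.
#' Significant islands are then classified into mutually exclusive
#' categories, evaluated in this order:
#'
#' * **paleo**: RPE significantly high (rare long branches concentrated);
#' * **neo**: RPE significantly low (rare short branches concentrated);
#' * **super**: both PE and PEalt in the highest `super_alpha` fraction of
#'   the null distribution (an extreme case of mixed endemism);
#' * **mixed**: both PE and PEalt significantly high, RPE in neither tail;
#' * **significant_other**: significant via the OR rule but matching none of
#'   the four categories (e.g. only PEalt high with mid RPE).
#'
#' Thresholds are inclusive (>= 1 - alpha, and for the neo rule
#' freq_lower >= 1 - alpha). No multiple-testing correction is applied
#' across islands.
#'
#' @param frequencies Tibble from [tail_frequencies()].
#' @param alpha Two-tailed significance level (default 0.05).
#' @param super_alpha Level for the super-endemism subdivision (default
#'   0.01); must be below `alpha`.
#' @return The input with a `category` factor column appended. Islands with
#'   any missing frequency get `NA` category and are flagged with a warning.
#' @export
assign_categories <- function(frequencies, alpha = 0.05, super_alpha = 0.01) {
  if (!(alpha > super_alpha && super_alpha > 0)) {
    abort("need alpha > super_alpha > 0", class = "islandpe_config_error")
  }
  fh_pe <- frequencies$freq_higher_pe
  fh_alt <- frequencies$freq_higher_pe_alt
  fh_rpe <- frequencies$freq_higher_rpe
  fl_rpe <- frequencies$freq_lower_rpe
  bad <- is.na(fh_pe) | is.na(fh_alt) | is.na(fh_rpe) | is.na(fl_rpe)
  sig <- fh_pe >= 1 - alpha | fh_alt >= 1 - alpha
  category <- dplyr::case_when(
    bad ~ NA_character_,
    !sig ~ "not_significant",
    fh_rpe >= 1 - alpha ~ "paleo",
    fl_rpe >= 1 - alpha ~ "neo",
    fh_pe >= 1 - super_alpha & fh_alt >= 1 - super_alpha ~ "super",
    fh_pe >= 1 - alpha & fh_alt >= 1 - alpha ~ "mixed",
    TRUE ~ "significant_other"
  )
  if (any(bad)) {
    warn(sprintf("%d island(s) unclassifiable (missing frequencies)", sum(bad)))
  }
  dplyr::mutate(frequencies,
                category = factor(category, levels = ENDEMISM_CATEGORIES))
}

#' Compare category assignments between the expanded and restricted variants
#'
#' @param assign_expanded,assign_restricted Tibbles from
#'   [assign_categories()] for the two variants; the restricted table covers
#'   only islands retained by [restrict_islands()].
#' @return Tibble with one row per expanded-variant island: `island_id`,
#'   `category_expanded`, `category_restricted` (`"excluded_R"` for islands
#'   absent from the restricted analysis), `changed`, and a `direction`
#'   label `"<expanded>-><restricted>"`.
#' @export
compare_variants <- function(assign_expanded, assign_restricted) {
  e <- dplyr::select(assign_expanded, "island_id",
                     category_expanded = "category")
  r <- dplyr::select(assign_restricted, "island_id",
                     category_restricted = "category")
  out <- dplyr::left_join(e, r, by = "island_id") |>
    dplyr::mutate(
      category_expanded = as.character(.data$category_expanded),
      category_restricted = dplyr::coalesce(
        as.character(.data$category_restricted), "excluded_R"),
      changed = .data$category_expanded != .data$category_restricted,
      direction = paste0(.data$category_expanded, "->",
                         .data$category_restricted)
    ) |>
    dplyr::arrange(.data$island_id)
  tibble::as_tibble(out)
}

#' Per-category counts and percentages
#'
#' Counts assigned islands per endemism category and expresses each count as
#' a percentage of the total number of islands analyzed. `significant` is
#' the number of islands in any of the four categories (paleo, neo, mixed,
#' super); `significant_other` islands are significant under the OR rule but
#' belong to none of the four categories and are reported separately.
#'
#' @param assignments Tibble with a `category` column (or a named vector /
#'   data frame of `category`, `count` pairs).
#' @param total_islands Denominator for the percentages (all islands
#'   analyzed).
#' @param digits Significant digits for the reported percentages (default 2,
#'   the reporting precision used for headline percentages).
#' @return Tibble with `category`, `count`, `percent`.
#' @export
#' @examples
#' summarize_categories(c(paleo = 16, neo = 10, mixed = 74, super = 42), 4306)
summarize_categories <- function(assignments, total_islands, digits = 2) {
  if (is.null(total_islands) || total_islands <= 0) {
    abort("`total_islands` must be positive", class = "islandpe_config_error")
  }
  if (is.data.frame(assignments) && all(c("category", "count") %in% names(assignments))) {
    counts <- setNames(assignments$count, as.character(assignments$category))
  } else if (is.numeric(assignments) && !is.null(names(assignments))) {
    counts <- assignments
  } else if (is.data.frame(assignments) && "category" %in% names(assignments)) {
    tab <- table(factor(assignments$category, levels = ENDEMISM_CATEGORIES))
    counts <- setNames(as.integer(tab), names(tab))
  } else {
    abort("`assignments` must have a category column or be a named count vector",
          class = "islandpe_config_error")
  }
  full <- setNames(numeric(length(ENDEMISM_CATEGORIES)), ENDEMISM_CATEGORIES)
  full[names(counts)] <- counts
  four <- c("paleo", "neo", "mixed", "super")
  out <- tibble::tibble(
    category = c(four, "significant", "significant_other", "not_significant"),
    count = unname(c(full[four], sum(full[four]), full["significant_other"],
                     full["not_significant"]))
  )
  if (sum(full) > total_islands) {
    abort("more assigned islands than `total_islands`",
          class = "islandpe_data_error")
  }
  dplyr::mutate(out, percent = signif(100 * .data$count / total_islands, digits))
}
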