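#' Remove records of genera flagged non-native in their island's region
#'
#' Islands map to region polygons (supplied as an id table); where a
#' (genus, region) pair is flagged non-native the occurrence is discarded.
#' Pairs with unknown status pass through to the bounding-box test, and
#' islands with no region mapping pass with a warning — the test cannot be
#' applied there.
#'
#' @param records Tibble with `genus` and `island_id` columns.
#' @param island_regions Tibble mapping `island_id` to `region_id`.
#' @param native_status Tibble with `genus`, `region_id`,
#'   `status` in `c("native", "non_native", "unknown")`.
#' @param quiet Suppress the per-rule count message.
#' @return Filtered records; attribute `filter_report` counts rows removed,
#'   untested (unknown status) and unmapped.
#' @export
filter_native_status <- function(records, island_regions, native_status,
                                 quiet = FALSE) {
  reg <- island_regions$region_id[match(records$island_id,
                                        island_regions$island_id)]
  key <- paste(records$genus, reg, sep = "\r")
  skey <- paste(native_status$genus, native_status$region_id, sep = "\r")
  status <- native_status$status[match(key, skey)]
  unmapped <- is.na(reg)
  if (any(unmapped) && !quiet) {
    warn(sprintf("%d record(s) on islands with no region mapping pass unfiltered",
                 sum(unmapped)))
  }
  drop <- !is.na(status) & status == "non_native"
  untested <- is.na(status) | status == "unknown"
  out <- records[!drop, , drop = FALSE]
  if (!quiet) {
    inform(sprintf("native-status filter: removed %d, untested %d of %d records",
                   sum(drop), sum(untested & !drop), nrow(records)))
  }
  attr(out, "filter_report") <- list(rule = "native_status",
                                     removed = sum(drop),
                                     untested = sum(untested & !drop),
                                     unmapped = sum(unmapped))
  out
}

# is lon inside [lon_min, lon_max], decomposed into two segments when the box
# crosses the antimeridian (lon_min > lon_max); boundary-inclusive
.lon_inside <- function(lon, lon_min, lon_max) {
  ifelse(lon_min <= lon_max,
         lon >= lon_min & lon <= lon_max,
         lon >= lon_min | lon <= lon_max)
}

#' Remove records outside their genus's native-range bounding box
#'
#' The native range of each genus is summarized as a latitude/longitude
#' bounding box; occurrences strictly outside the box are discarded.
#' Boundary points are retained. Boxes crossing the antimeridian are encoded
#' with `lon_min > lon_max` and treated as the union of the two longitude
#' segments `[lon_min, 180]` and `[-180, lon_max]`. Genera without a box
#' pass with a warning.
#'
#' @param records Tibble with `genus`, `latitude`, `longitude`.
#' @param annotations Tibble with `genus`, `lat_min`, `lat_max`, `lon_min`,
#'   `lon_max` (degrees, longitudes in \[-180, 180\]).
#' @param quiet Suppress messages.
#' @return Filtered records with a `filter_report` attribute.
#' @export
filter_bounding_box <- function(records, annotations, quiet = FALSE) {
  need <- c("genus", "lat_min", "lat_max", "lon_min", "lon_max")
  if (!all(need %in% names(annotations))) {
    abort("`annotations` must have genus, lat_min, lat_max, lon_min, lon_max",
          class = "islandpe_config_error")
  }
  if (any(annotations$lat_min > annotations$lat_max, na.rm = TRUE)) {
    bad <- annotations$genus[which(annotations$lat_min > annotations$lat_max)]
    abort(paste0("Bounding box with lat_min > lat_max for: ",
                 paste(head(bad, 5), collapse = ", ")),
          class = "islandpe_config_error")
  }
  i <- match(records$genus, annotations$genus)
  has_box <- !is.na(i) & !is.na(annotations$lat_min[i])
  if (any(!has_box) && !quiet) {
    warn(sprintf("%d record(s) of genera without a bounding box pass unfiltered",
                 sum(!has_box)))
  }
  inside <- rep(TRUE, nrow(records))
  j <- which(has_box)
  ij <- i[j]
  inside[j] <- records$latitude[j] >= annotations$lat_min[ij] &
    records$latitude[j] <= annotations$lat_max[ij] &
    .lon_inside(records$longitude[j], annotations$lon_min[ij],
                annotations$lon_max[ij])
  out <- records[inside, , drop = FALSE]
  if (!quiet) {
    inform(sprintf("bounding-box filter: removed %d of %d records",
                   sum(!inside), nrow(records)))
  }
  attr(out, "filter_report") <- list(rule = "bounding_box",
                                     removed = sum(!inside),
                                     untested = sum(!has_box))
  out
}

#' Fit a species-area richness model
#'
#' Least-squares fit of `log10(richness)` on `log10(area)`, optionally with
#' `log10(1 + distance)` (isolation) as a second predictor. Predictions are
#' back-transformed to counts. The island species-area relationship is the
#' standard baseline predictor of insular richness; the model is used only to
#' flag under-sampled islands, and is pluggable — any object with a
#' `predict_richness()` method works downstream.
#'
#' @param island_table Tibble with `island_id`, `richness` (> 0 observed
#'   count), `area` (> 0, km2) and optionally `distance` (km to the nearest
#'   continent).
#' @param use_isolation Include the isolation covariate (default `FALSE`).
#' @return Object of class `richness_model` wrapping the `lm` fit, with the
#'   per-island predictions in `$fitted` and a reliability flag.
#' @export
fit_richness_model <- function(island_table, use_isolation = FALSE) {
  need <- c("island_id", "richness", "area")
  if (!all(need %in% names(island_table))) {
    abort("`island_table` needs island_id, richness, area",
          class = "islandpe_config_error")
  }
  d <- dplyr::filter(island_table, .data$richness > 0, .data$area > 0)
  if (nrow(d) < 2 || length(unique(d$area)) < 2) {
    abort("Degenerate design: need >= 2 islands with distinct positive areas",
          class = "islandpe_data_error")
  }
  unreliable <- nrow(d) < 10
  if (unreliable) {
    warn(sprintf("richness model fitted on only %d islands: unreliable", nrow(d)))
  }
  fml <- if (use_isolation && "distance" %in% names(island_table)) {
    log10(richness) ~ log10(area) + log10(1 + distance)
  } else {
    log10(richness) ~ log10(area)
  }
  fit <- lm(fml, data = d)
  structure(
    list(fit = fit,
         use_isolation = use_isolation && "distance" %in% names(island_table),
         n = nrow(d), unreliable = unreliable,
         fitted = tibble::tibble(island_id = d$island_id,
                                 predicted = 10^fitted(fit))),
    class = "richness_model"
  )
}

#' Predict richness for islands
#' @param model A `richness_model`.
#' @param island_table Tibble with `area` (and `distance` if the model uses
#'   isolation).
#' @return Numeric vector of predicted richness counts (strictly positive).
#' @export
predict_richness <- function(model, island_table) {
  stopifnot(inherits(model, "richness_model"))
  unname(10^predict(model$fit, newdata = island_table))
}

#' @export
print.richness_model <- function(x, ...) {
  cf <- coef(x$fit)
  cat(sprintf("<richness_model> log10(S) ~ log10(A)%s on %d islands\n",
              if (x$use_isolation) " + log10(1+D)" else "", x$n))
  cat(sprintf("  intercept %.4g, area exponent %.4g%s\n", cf[1], cf[2],
              if (x$unreliable) "  [unreliable]" else ""))
  invisible(x)
}

#' Exclude under-sampled islands
#'
#' An island is excluded when its observed richness falls below the model
#' prediction divided by `factor` (default 5) — observed counts that far
#' under the species-area expectation indicate under-sampling rather than
#' genuine poverty. Retention is boundary-inclusive: observed exactly equal
#' to predicted/factor is retained.
#'
#' @param island_table Tibble with `island_id`, `richness`, `area` (and
#'   `distance` if the model uses isolation).
#' @param model A `richness_model` (see [fit_richness_model()]).
#' @param factor Exclusion factor, must exceed 1 (default 5).
#' @return List with `retained` (character island ids) and `report` (tibble
#'   of excluded islands with observed and predicted richness).
#' @export
exclude_undersampled <- function(island_table, model, factor = 5) {
  if (factor <= 1) abort("`factor` must be > 1", class = "islandpe_config_error")
  pred <- predict_richness(model, island_table)
  excluded <- island_table$richness < pred / factor
  list(
    retained = island_table$island_id[!excluded],
    report = tibble::tibble(
      island_id = island_table$island_id[excluded],
      observed = island_table$richness[excluded],
      predicted = pred[excluded]
    )
  )
}

#' Incidence-based coverage estimator (ICE) per island
#'
#' Estimates sampling completeness per island from taxon incidence
#' frequencies across sampling units (collection events, grid cells, or
#' generator-defined visits). Taxa found in more than `cutoff` units are
#' "frequent"; the ICE richness estimate is
#' `S_ice = S_freq + S_infreq / C_ice + Q1 * g2 / C_ice`, where
#' `C_ice = 1 - Q1 / N_infreq` is the sample incidence coverage, `Q_j` the
#' number of taxa found in exactly `j` units, `N_infreq` the total incidences
#' of infrequent taxa, and `g2` the squared coefficient of variation of the
#' infrequent incidence counts,
#' `g2 = max(S_infreq/C_ice * m/(m-1) * sum(j(j-1)Q_j) / N_infreq^2 - 1, 0)`
#' with `m` the number of units holding at least one infrequent taxon. The
#' relative coverage is `ICEr = S_obs / S_ice`.
#'
#' Degenerate inputs: with no infrequent taxa `ICEr = 1`; when every
#' infrequent incidence is a singleton (`C_ice = 0`) the estimate falls back
#' to a Chao2-type estimator `S_obs + (m-1)/m * Q1*(Q1-1) / (2*(Q2+1))` and
#' the score is flagged `unstable`; islands with zero sampling units are
#' flagged `undefined`.
#'
#' @param incidence_freq Tibble with `island_id`, `taxon`, `n_units` (number
#'   of sampling units in which the taxon was recorded on that island).
#' @param units_per_island Optional tibble `island_id`, `n_units_total`;
#'   defaults to the maximum taxon frequency per island.
#' @param cutoff Infrequent-taxon cutoff (default 10 units).
#' @return Tibble with `island_id`, `s_obs`, `s_ice`, `icer`, `flag`
#'   (`"ok"`, `"unstable"` or `"undefined"`).
#' @export
ice_coverage <- function(incidence_freq, units_per_island = NULL, cutoff = 10) {
  need <- c("island_id", "taxon", "n_units")
  if (!all(need %in% names(incidence_freq))) {
    abort("`incidence_freq` needs island_id, taxon, n_units",
          class = "islandpe_config_error")
  }
  one <- function(d, m_units = NULL) {
    f <- d$n_units
    s_obs <- nrow(d)
    if (s_obs == 0 || all(f <= 0)) {
      return(tibble::tibble(s_obs = s_obs, s_ice = NA_real_,
                            icer = NA_real_, flag = "undefined"))
    }
    infreq <- f <= cutoff
    s_freq <- sum(!infreq)
    s_inf <- sum(infreq)
    if (s_inf == 0) {
      return(tibble::tibble(s_obs = s_obs, s_ice = as.numeric(s_obs),
                            icer = 1, flag = "ok"))
    }
    fi <- f[infreq]
    n_inf <- sum(fi)
    q1 <- sum(fi == 1)
    q2 <- sum(fi == 2)
    # number of sampling units carrying infrequent taxa; the caller-supplied
    # unit count when available, else the max frequency as a lower bound
    m <- if (!is.null(m_units)) m_units else max(fi)
    c_ice <- 1 - q1 / n_inf
    if (c_ice <= 0) {
      s_ice <- s_obs + (if (m > 1) (m - 1) / m else 1) * q1 * (q1 - 1) / (2 * (q2 + 1))
      s_ice <- max(s_ice, s_obs)
      return(tibble::tibble(s_obs = s_obs, s_ice = s_ice,
                            icer = s_obs / s_ice, flag = "unstable"))
    }
    g2 <- if (m > 1) {
      max(s_inf / c_ice * m / (m - 1) * sum(fi * (fi - 1)) / n_inf^2 - 1, 0)
    } else 0
    s_ice <- s_freq + s_inf / c_ice + q1 * g2 / c_ice
    s_ice <- max(s_ice, s_obs)
    tibble::tibble(s_obs = s_obs, s_ice = s_ice, icer = s_obs / s_ice,
                   flag = "ok")
  }
  split_units <- if (!is.null(units_per_island)) {
    setNames(units_per_island$n_units_total, units_per_island$island_id)
  } else NULL
  incidence_freq |>
    dplyr::group_by(.data$island_id) |>
    dplyr::group_modify(function(d, key) {
      m_units <- if (!is.null(split_units) && key$island_id %in% names(split_units)) {
        unname(split_units[key$island_id])
      } else NULL
      one(d, m_units)
    }) |>
    dplyr::ungroup()
}
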