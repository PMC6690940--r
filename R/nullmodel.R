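#' Fixed row- and column-sum randomizations of an incidence matrix
#'
#' Draws binary matrices with exactly the observed marginals — each island
#' keeps its number of genera and each genus keeps its number of islands —
#' using curveball trades (pairwise row trades of non-shared presences) on a
#' single sequential chain: `burn_in` trades before the first sample and
#' `thinning` trades between samples. With `burn_in = 0` and `thinning = 0`
#' the chain has taken no step and every sample equals the observed matrix.
#'
#' @param incidence Binary islands x genera matrix.
#' @param n_sims Number of matrices to draw.
#' @param seed Integer seed; the stream is reproducible from it.
#' @param burn_in Trades discarded before the first sample; default
#'   `5 * sum(incidence)`.
#' @param thinning Trades between successive samples; default
#'   `sum(incidence)`.
#' @return A 3-d array (islands x genera x n_sims) with dimnames.
#' @export
randomize_fixed_fixed <- function(incidence, n_sims, seed = NULL,
                                  burn_in = NULL, thinning = NULL) {
  validate_incidence(incidence)
  if (n_sims < 1) abort("`n_sims` must be at least 1", class = "islandpe_config_error")
  fill <- sum(incidence)
  if (is.null(burn_in)) burn_in <- 5L * fill
  if (is.null(thinning)) thinning <- fill
  if (burn_in < 0 || thinning < 0) {
    abort("`burn_in` and `thinning` must be non-negative",
          class = "islandpe_config_error")
  }
  if (burn_in == 0 && thinning == 0) {
    sims <- array(rep(incidence, n_sims),
                  dim = c(nrow(incidence), ncol(incidence), n_sims))
    dimnames(sims) <- c(dimnames(incidence), list(paste0("sim_", seq_len(n_sims))))
    return(sims)
  }
  nm <- vegan::nullmodel(incidence, "curveball")
  sims <- stats::simulate(nm, nsim = n_sims, seed = seed,
                          burnin = burn_in, thin = max(1L, thinning))
  dimnames(sims) <- c(dimnames(incidence), list(paste0("sim_", seq_len(n_sims))))
  sims
}

#' Null distributions of PE, PEalt and RPE
#'
#' Recomputes branch ranges and the three metrics from scratch on each
#' fixed-marginal randomization of the incidence matrix. Continental flags
#' travel with the genera (columns) and `n_max` is held fixed, so the
#' restricted weighting rule is re-applied to every randomized matrix. RPE
#' under the null is the ratio of the simulated PE and PEalt.
#'
#' @inheritParams endemism_scores
#' @param n_sims Number of randomizations (default 1000).
#' @param seed Integer seed for the randomizer.
#' @param burn_in,thinning Chain controls, see [randomize_fixed_fixed()].
#' @param keep_samples Keep the full per-island null samples (debug;
#'   default `FALSE`, streaming tail counters only).
#' @param obs_scale Optional per-island multiplier applied to the observed
#'   metrics before tail counting (the `divide_observed` coverage-correction
#'   mode passes `1/ICEr` here); named by island id or in row order.
#' @return An object of class `null_ensemble`: a list with the observed
#'   `scores` tibble, tail-count tibble `counts` (per island: number of
#'   simulations in which the observed metric was strictly greater / strictly
#'   less than the simulated one), `n_sims`, `null_total_pe` (per-sim totals),
#'   and `samples` (islands x 3 metrics x n_sims array) if requested.
#' @export
null_metric_distribution <- function(tree, incidence, annotations = NULL,
                                     variant = c("expanded", "restricted"),
                                     n_sims = 1000, seed = NULL,
                                     n_max = NULL, l_uniform = NULL,
                                     burn_in = NULL, thinning = NULL,
                                     terminal_only = FALSE,
                                     keep_samples = FALSE,
                                     obs_scale = NULL) {
  variant <- match.arg(variant)
  if (n_sims < 1) abort("`n_sims` must be at least 1", class = "islandpe_config_error")
  struct <- branch_structure(tree)
  if (is.null(l_uniform)) l_uniform <- mean(struct$lengths)
  obs_ranges <- ranges_from_struct(struct, incidence, annotations, variant,
                                   n_max, terminal_only)
  observed <- scores_from_ranges(obs_ranges, incidence, variant, l_uniform)
  sims <- randomize_fixed_fixed(incidence, n_sims, seed, burn_in, thinning)

  n_isl <- nrow(incidence)
  gt <- matrix(0L, n_isl, 3, dimnames = list(rownames(incidence),
                                             c("pe", "pe_alt", "rpe")))
  lt <- gt
  null_total_pe <- numeric(n_sims)
  samples <- if (keep_samples) {
    array(NA_real_, c(n_isl, 3, n_sims),
          dimnames = list(rownames(incidence), c("pe", "pe_alt", "rpe"), NULL))
  } else NULL
  obs <- cbind(observed$pe, observed$pe_alt, observed$rpe)
  if (!is.null(obs_scale)) {
    sc <- if (!is.null(names(obs_scale))) {
      unname(obs_scale[rownames(incidence)])
    } else obs_scale
    obs <- obs * sc
  }
  for (s in seq_len(n_sims)) {
    xs <- sims[, , s, drop = TRUE]
    if (is.null(dim(xs))) xs <- matrix(xs, n_isl, ncol(incidence),
                                       dimnames = dimnames(incidence))
    r <- ranges_from_struct(struct, xs, annotations, variant, n_max,
                            terminal_only)
    sc <- scores_from_ranges(r, xs, variant, l_uniform)
    sim <- cbind(sc$pe, sc$pe_alt, sc$rpe)
    gt <- gt + (obs > sim)
    lt <- lt + (obs < sim)
    null_total_pe[s] <- sum(sc$pe)
    if (keep_samples) samples[, , s] <- sim
  }
  counts <- tibble::tibble(
    island_id = rownames(incidence),
    variant = variant,
    gt_pe = unname(gt[, "pe"]), lt_pe = unname(lt[, "pe"]),
    gt_pe_alt = unname(gt[, "pe_alt"]), lt_pe_alt = unname(lt[, "pe_alt"]),
    gt_rpe = unname(gt[, "rpe"]), lt_rpe = unname(lt[, "rpe"])
  )
  structure(
    list(scores = observed, counts = counts, n_sims = n_sims,
         variant = variant, seed = seed, l_uniform = l_uniform,
         null_total_pe = null_total_pe, samples = samples),
    class = "null_ensemble"
  )
}

#' @export
print.null_ensemble <- function(x, ...) {
  cat(sprintf("<null_ensemble> %s variant, %d islands, %d simulations\n",
              x$variant, nrow(x$scores), x$n_sims))
  invisible(x)
}

#' Tail frequencies of observed metrics against the null ensemble
#'
#' For each island and metric, the proportion of simulations in which the
#' observed value was strictly greater (`freq_higher_*`) or strictly less
#' (`freq_lower_*`) than the simulated value. Ties count in neither tail, so
#' the two frequencies sum to at most 1; the tie policy is conservative
#' toward non-significance.
#'
#' @param ensemble A `null_ensemble` from [null_metric_distribution()].
#' @return Tibble with one row per island: `island_id`, `variant`,
#'   `freq_higher_pe`, `freq_lower_pe`, `freq_higher_pe_alt`,
#'   `freq_lower_pe_alt`, `freq_higher_rpe`, `freq_lower_rpe`, `n_sims`.
#' @export
tail_frequencies <- function(ensemble) {
  if (!inherits(ensemble, "null_ensemble")) {
    abort("`ensemble` must come from null_metric_distribution()",
          class = "islandpe_config_error")
  }
  n <- ensemble$n_sims
  ensemble$counts |>
    dplyr::transmute(
      .data$island_id, .data$variant,
      freq_higher_pe = .data$gt_pe / n,
      freq_lower_pe = .data$lt_pe / n,
      freq_higher_pe_alt = .data$gt_pe_alt / n,
      freq_lower_pe_alt = .data$lt_pe_alt / n,
      freq_higher_rpe = .data$gt_rpe / n,
      freq_lower_rpe = .data$lt_rpe / n,
      n_sims = n
    )
}
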