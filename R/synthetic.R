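#' Define a synthetic endemism scenario
#'
#' A scenario fixes every knob of the synthetic world: the genus-level Yule
#' tree with designated rare long-branch (paleo) and short-branch (neo) tip
#' pools, the right-skewed island-occupancy model, the continental fraction,
#' and the islands where endemism signal is planted. All generation is fully
#' deterministic given the scenario (per-stage seeds are derived from the one
#' top-level seed).
#'
#' @param n_genera Number of genus tips (default 300).
#' @param n_islands Number of islands (default 200).
#' @param seed Top-level integer seed.
#' @param f_paleo,f_neo Fractions of tips assigned to the long-branch and
#'   short-branch rare pools (defaults 0.06 each).
#' @param m_long Terminal-branch length multiplier of the paleo pool
#'   (default 5, must be >= 3 for a detectable old-lineage signal).
#' @param m_short Multiplier of the neo pool (default 0.2, <= 1/3).
#' @param occupancy_exponent Exponent of the truncated power-law
#'   islands-per-genus distribution (default 2; occurrence data are strongly
#'   right-skewed and rarity is the lever of endemism).
#' @param pool_max_islands Maximum islands a pool genus occupies (default 2).
#' @param continental_fraction Fraction of genera flagged as also occurring
#'   on a continent; flags are given to the most widespread non-pool genera
#'   (default 0.3).
#' @param paleo_islands,neo_islands,mixed_islands Integer indices (1-based)
#'   of islands where signal is planted; disjoint.
#' @param kappa Concentration: probability that a pool genus is placed on its
#'   designated planted island(s) rather than at random (default 1).
#' @param genera_per_planted Pool genera designated per planted island
#'   (default 3).
#' @return Object of class `endemism_scenario`.
#' @export
endemism_scenario <- function(n_genera = 300, n_islands = 200, seed = 1,
                              f_paleo = 0.06, f_neo = 0.06,
                              m_long = 5, m_short = 0.2,
                              occupancy_exponent = 2,
                              pool_max_islands = 2,
                              continental_fraction = 0.3,
                              paleo_islands = integer(),
                              neo_islands = integer(),
                              mixed_islands = integer(),
                              kappa = 1,
                              genera_per_planted = 3) {
  stopifnot(n_genera >= 2, n_islands >= 2,
            f_paleo >= 0, f_paleo <= 1, f_neo >= 0, f_neo <= 1,
            m_long > 0, m_short > 0, kappa >= 0, kappa <= 1,
            continental_fraction >= 0, continental_fraction <= 1,
            pool_max_islands >= 1)
  planted <- c(paleo_islands, neo_islands, mixed_islands)
  if (anyDuplicated(planted)) {
    abort("planted island lists must be disjoint", class = "islandpe_config_error")
  }
  if (length(planted) && (max(planted) > n_islands || min(planted) < 1)) {
    abort("planted island indices out of range", class = "islandpe_config_error")
  }
  structure(
    list(n_genera = n_genera, n_islands = n_islands, seed = as.integer(seed),
         f_paleo = f_paleo, f_neo = f_neo, m_long = m_long, m_short = m_short,
         occupancy_exponent = occupancy_exponent,
         pool_max_islands = pool_max_islands,
         continental_fraction = continental_fraction,
         paleo_islands = as.integer(paleo_islands),
         neo_islands = as.integer(neo_islands),
         mixed_islands = as.integer(mixed_islands),
         kappa = kappa, genera_per_planted = genera_per_planted),
    class = "endemism_scenario"
  )
}

island_ids <- function(scenario) sprintf("I%04d", seq_len(scenario$n_islands))
genus_ids <- function(scenario) sprintf("G%04d", seq_len(scenario$n_genera))

# stage seeds derived from the top-level seed; kept well below 2^31
stage_seed <- function(scenario, stage) {
  (scenario$seed * 101L + stage * 7919L) %% 2000000011L
}

#' Generate the dated genus tree of a scenario
#'
#' Pure-birth (Yule) tree; designated paleo-pool tips have their terminal
#' branch lengths multiplied by `m_long` and neo-pool tips by `m_short`,
#' giving direct control of the rare long-branch and rare short-branch pools
#' that carry the paleo/neo signal.
#'
#' @param scenario An [endemism_scenario()].
#' @return An [ape::phylo] with tip labels `G0001...`; attribute `pools` is a
#'   tibble (`genus`, `pool` in background/paleo/neo).
#' @export
generate_tree <- function(scenario) {
  stopifnot(inherits(scenario, "endemism_scenario"))
  set.seed(stage_seed(scenario, 1L))
  n <- scenario$n_genera
  tree <- if (n == 2) {
    ape::read.tree(text = "(G0001:1,G0002:1);")
  } else {
    ape::rphylo(n, birth = 1, death = 0)
  }
  tree$tip.label <- genus_ids(scenario)
  n_paleo <- round(scenario$f_paleo * n)
  n_neo <- round(scenario$f_neo * n)
  pick <- sample.int(n, n_paleo + n_neo)
  pool <- rep("background", n)
  pool[pick[seq_len(n_paleo)]] <- "paleo"
  pool[pick[n_paleo + seq_len(n_neo)]] <- "neo"
  term <- match(seq_len(n), tree$edge[, 2]) # terminal edge of each tip
  tree$edge.length[term[pool == "paleo"]] <-
    tree$edge.length[term[pool == "paleo"]] * scenario$m_long
  tree$edge.length[term[pool == "neo"]] <-
    tree$edge.length[term[pool == "neo"]] * scenario$m_short
  attr(tree, "pools") <- tibble::tibble(genus = tree$tip.label, pool = pool)
  tree
}

# truncated power-law sampler for islands-per-genus
sample_occupancy <- function(n, n_islands, exponent) {
  k <- seq_len(n_islands)
  sample(k, n, replace = TRUE, prob = k^(-exponent))
}

#' Generate the island-by-genus incidence matrix of a scenario
#'
#' Islands-per-genus counts follow the truncated power law; pool genera are
#' rare (at most `pool_max_islands` islands). Each pool genus is designated a
#' planted island of its class (round-robin over the planted list; mixed
#' islands are served by both pools) and is placed there with probability
#' `kappa`, otherwise uniformly at random. Background genera are placed
#' uniformly. Empty islands receive one background presence so that every
#' island carries at least one genus. Continental flags go to the most
#' widespread non-pool genera.
#'
#' @param scenario An [endemism_scenario()].
#' @param tree Output of [generate_tree()] for the same scenario.
#' @return List with `incidence` (binary matrix islands x genera),
#'   `annotations` (tibble `genus`, `continental`, `pool`).
#' @export
generate_incidence <- function(scenario, tree) {
  stopifnot(inherits(scenario, "endemism_scenario"))
  pools <- attr(tree, "pools")
  if (is.null(pools)) abort("`tree` must come from generate_tree()",
                            class = "islandpe_config_error")
  set.seed(stage_seed(scenario, 2L))
  n_g <- scenario$n_genera
  n_i <- scenario$n_islands
  isl <- island_ids(scenario)
  gen <- genus_ids(scenario)
  pool <- pools$pool

  occ <- sample_occupancy(n_g, n_i, scenario$occupancy_exponent)
  occ[pool != "background"] <- pmin(occ[pool != "background"],
                                    scenario$pool_max_islands)

  # designate planted targets round-robin within each pool
  target <- rep(NA_integer_, n_g)
  assign_targets <- function(pool_name, planted) {
    idx <- which(pool == pool_name)
    planted_all <- c(planted, scenario$mixed_islands)
    if (!length(planted_all) || !length(idx)) return()
    need <- rep(planted_all, each = scenario$genera_per_planted)
    n_use <- min(length(idx), length(need))
    if (length(need) > length(idx)) {
      abort(sprintf("pool '%s' too small for requested planting (%d needed, %d available)",
                    pool_name, length(need), length(idx)),
            class = "islandpe_generation_error")
    }
    target[idx[seq_len(n_use)]] <<- need[seq_len(n_use)]
  }
  assign_targets("paleo", scenario$paleo_islands)
  assign_targets("neo", scenario$neo_islands)

  m <- matrix(0L, n_i, n_g, dimnames = list(isl, gen))
  for (g in seq_len(n_g)) {
    k <- occ[g]
    if (!is.na(target[g]) && runif(1) < scenario$kappa) {
      where <- target[g]
      if (k > 1) {
        extra <- sample(setdiff(seq_len(n_i), where), k - 1)
        where <- c(where, extra)
      }
    } else {
      where <- sample.int(n_i, k)
    }
    m[where, g] <- 1L
  }
  empty <- which(rowSums(m) == 0)
  if (length(empty)) {
    bg <- which(pool == "background")
    fill <- sample(bg, length(empty), replace = TRUE)
    m[cbind(empty, fill)] <- 1L
  }
  n_cont <- round(scenario$continental_fraction * n_g)
  bg <- which(pool == "background")
  n_cont <- min(n_cont, length(bg))
  continental <- rep(FALSE, n_g)
  if (n_cont > 0) {
    w <- colSums(m)[bg]
    continental[sample(bg, n_cont, prob = w + 0.5)] <- TRUE
  }
  list(
    incidence = m,
    annotations = tibble::tibble(genus = gen, continental = continental,
                                 pool = pool)
  )
}

#' Generate occurrence records (with optional injected noise)
#'
#' Lays the islands out as points on a synthetic globe, emits 1 to
#' `max_records` occurrence records per presence at the island position with
#' a small jitter, and derives each genus's native bounding box from the
#' positions of its islands plus a margin. Noise exercises the cleaning
#' filters: `out_of_box_fraction` adds spurious records of a genus on islands
#' far outside its native box, and `non_native_fraction` adds records on
#' islands outside its range whose (genus, region) pair is flagged
#' non-native. Inverting both filters must recover the clean incidence
#' exactly; the injected rows are book-kept in the `noise` column.
#'
#' @param scenario An [endemism_scenario()].
#' @param incidence Output of [generate_incidence()].
#' @param out_of_box_fraction,non_native_fraction Noise record counts as a
#'   fraction of the number of presences (defaults 0).
#' @param max_records Maximum records per presence (default 3).
#' @return List with `records` (tibble `genus`, `island_id`, `latitude`,
#'   `longitude`, `noise`), `islands` (tibble `island_id`, `latitude`,
#'   `longitude`, `region_id`, `area`), `island_regions`, `native_status`,
#'   and `annotations` (genus boxes + continental flags).
#' @export
generate_occurrence_records <- function(scenario, incidence,
                                        out_of_box_fraction = 0,
                                        non_native_fraction = 0,
                                        max_records = 3) {
  stopifnot(inherits(scenario, "endemism_scenario"))
  set.seed(stage_seed(scenario, 3L))
  m <- incidence$incidence
  ann <- incidence$annotations
  isl <- rownames(m)
  gen <- colnames(m)
  n_i <- length(isl)
  islands <- tibble::tibble(
    island_id = isl,
    latitude = runif(n_i, -60, 70),
    longitude = runif(n_i, -180, 180),
    region_id = NA_character_,
    area = 10^runif(n_i, 0, 4)
  )
  islands$region_id <- sprintf("R%02d", floor((islands$longitude + 180) / 30))
  pres <- which(m == 1L, arr.ind = TRUE)
  reps <- sample.int(max_records, nrow(pres), replace = TRUE)
  ri <- rep(pres[, 1], reps)
  rg <- rep(pres[, 2], reps)
  records <- tibble::tibble(
    genus = gen[rg],
    island_id = isl[ri],
    latitude = pmin(90, pmax(-90, islands$latitude[ri] + runif(length(ri), -0.1, 0.1))),
    longitude = pmin(180, pmax(-180, islands$longitude[ri] + runif(length(ri), -0.1, 0.1))),
    noise = "none"
  )
  # native bounding boxes from the generating positions plus a margin
  margin <- 1
  boxes <- purrr::map_dfr(seq_along(gen), function(g) {
    on <- which(m[, g] == 1L)
    tibble::tibble(
      genus = gen[g],
      lat_min = min(islands$latitude[on]) - margin,
      lat_max = max(islands$latitude[on]) + margin,
      lon_min = max(-180, min(islands$longitude[on]) - margin),
      lon_max = min(180, max(islands$longitude[on]) + margin)
    )
  })
  native_status <- tibble::tibble(genus = character(), region_id = character(),
                                  status = character())
  n_pres <- nrow(pres)
  inject <- function(n_noise, kind) {
    if (n_noise < 1) return(NULL)
    out <- vector("list", n_noise)
    for (j in seq_len(n_noise)) {
      g <- sample.int(length(gen), 1)
      off_range <- which(m[, g] == 0L)
      if (!length(off_range)) next
      if (kind == "out_of_box") {
        b <- boxes[g, ]
        far <- off_range[islands$latitude[off_range] > b$lat_max + 1 |
                           islands$latitude[off_range] < b$lat_min - 1]
        if (!length(far)) next
        i <- sample(rep(far, 2), 1)
      } else {
        i <- sample(rep(off_range, 2), 1)
      }
      out[[j]] <- tibble::tibble(
        genus = gen[g], island_id = isl[i],
        latitude = islands$latitude[i], longitude = islands$longitude[i],
        noise = kind
      )
    }
    dplyr::bind_rows(out)
  }
  oob <- inject(round(out_of_box_fraction * n_pres), "out_of_box")
  nn <- inject(round(non_native_fraction * n_pres), "non_native")
  if (!is.null(nn) && nrow(nn)) {
    native_status <- dplyr::distinct(
      tibble::tibble(genus = nn$genus,
                     region_id = islands$region_id[match(nn$island_id, islands$island_id)],
                     status = "non_native"))
    # never flag a region where the genus genuinely occurs
    real <- dplyr::distinct(
      tibble::tibble(genus = records$genus,
                     region_id = islands$region_id[match(records$island_id,
                                                         islands$island_id)]))
    native_status <- dplyr::anti_join(native_status, real,
                                      by = c("genus", "region_id"))
    nn$region_id <- islands$region_id[match(nn$island_id, islands$island_id)]
    nn <- dplyr::semi_join(nn, native_status, by = c("genus", "region_id"))
    nn$region_id <- NULL
  }
  records <- dplyr::bind_rows(records, oob, nn)
  list(
    records = records,
    islands = islands,
    island_regions = dplyr::select(islands, "island_id", "region_id"),
    native_status = native_status,
    annotations = dplyr::left_join(ann, boxes, by = "genus")
  )
}

#' Generate a full synthetic dataset
#'
#' Convenience wrapper running [generate_tree()], [generate_incidence()] and
#' (optionally) [generate_occurrence_records()] for one scenario.
#'
#' @param scenario An [endemism_scenario()].
#' @param with_records Also generate occurrence records (default `FALSE`).
#' @param ... Passed to [generate_occurrence_records()].
#' @return List with `tree`, `incidence`, `annotations`, `scenario`, and the
#'   record-level tables when requested.
#' @export
synthesize_dataset <- function(scenario, with_records = FALSE, ...) {
  tree <- generate_tree(scenario)
  inc <- generate_incidence(scenario, tree)
  out <- list(tree = tree, incidence = inc$incidence,
              annotations = inc$annotations, scenario = scenario)
  if (with_records) {
    rec <- generate_occurrence_records(scenario, inc, ...)
    out$annotations <- rec$annotations # genus flags plus native-range boxes
    out <- c(out, rec[setdiff(names(rec), "annotations")])
  }
  out
}

#' Synthetic species-area island table
#'
#' Islands whose richness follows `richness = intercept * area^exponent`
#' with optional lognormal noise; used to exercise the species-area richness
#' model and the under-sampling exclusion rule.
#'
#' @param n Number of islands.
#' @param seed Integer seed.
#' @param intercept,exponent Power-law parameters (defaults 3 and 0.25).
#' @param sigma Standard deviation of the lognormal (log10) noise; 0 gives
#'   exact power-law richness.
#' @return Tibble with `island_id`, `area`, `richness`.
#' @export
generate_island_table <- function(n, seed = 1, intercept = 3,
                                  exponent = 0.25, sigma = 0) {
  set.seed(seed)
  area <- 10^runif(n, 0, 5)
  richness <- intercept * area^exponent * 10^rnorm(n, 0, sigma)
  tibble::tibble(island_id = sprintf("I%04d", seq_len(n)),
                 area = area, richness = richness)
}

#' Planted-versus-assigned recovery report
#'
#' Confusion table of the planted island classes of a scenario against the
#' categories the pipeline assigned, with per-class recall and the
#' false-positive rate among unplanted islands. A planted mixed island counts
#' as recovered when assigned mixed or super (super is the extreme
#' subdivision of mixed).
#'
#' @param assignments Tibble from [assign_categories()] (columns `island_id`,
#'   `category`).
#' @param scenario The [endemism_scenario()] that generated the data.
#' @return List with `summary` (per planted class: `n_planted`,
#'   `n_recovered`, `recall`), `false_positive_rate` (share of unplanted
#'   islands in any of the four categories), and `confusion` (table).
#' @export
recovery_report <- function(assignments, scenario) {
  isl <- island_ids(scenario)
  planted <- rep("unplanted", length(isl))
  planted[scenario$paleo_islands] <- "paleo"
  planted[scenario$neo_islands] <- "neo"
  planted[scenario$mixed_islands] <- "mixed"
  cat_of <- as.character(assignments$category)[match(isl, assignments$island_id)]
  cat_of[is.na(cat_of)] <- "not_significant"
  confusion <- table(planted = planted, assigned = cat_of)
  recovered <- function(class) {
    idx <- planted == class
    hits <- if (class == "mixed") cat_of[idx] %in% c("mixed", "super")
    else cat_of[idx] == class
    c(n_planted = sum(idx), n_recovered = sum(hits))
  }
  classes <- intersect(c("paleo", "neo", "mixed"), unique(planted))
  summary <- purrr::map_dfr(classes, function(cl) {
    r <- recovered(cl)
    tibble::tibble(class = cl, n_planted = r[["n_planted"]],
                   n_recovered = r[["n_recovered"]],
                   recall = r[["n_recovered"]] / max(1, r[["n_planted"]]))
  })
  un <- planted == "unplanted"
  fp <- mean(cat_of[un] %in% c("paleo", "neo", "mixed", "super"))
  list(summary = summary, false_positive_rate = fp, confusion = confusion)
}
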