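#' Read a dated phylogeny from a Newick file
#'
#' Reads a rooted tree with branch lengths (in millions of years) and genus
#' names at the tips. Polytomies are permitted; the tree need not be fully
#' resolved. The tree is validated before it is returned: tip labels must be
#' unique and non-empty, and every edge must carry a non-negative length.
#'
#' @param path Path to a Newick file. A root edge, if present in the file, is
#'   kept on the `phylo` object but is ignored by all downstream metrics.
#' @param quiet Suppress the tip-count message.
#' @return An [ape::phylo] object.
#' @export
#' @examples
#' tf <- tempfile(fileext = ".nwk")
#' writeLines("((A:1,B:1):1,C:2);", tf)
#' tr <- read_newick(tf)
read_newick <- function(path, quiet = FALSE) {
  if (!file.exists(path)) {
    abort(paste0("Newick file not found: ", path), class = "islandpe_io_error")
  }
  # ape warns and returns NULL on some malformed inputs; we raise our own
  # parse error either way
  tree <- tryCatch(
    suppressWarnings(ape::read.tree(path)),
    error = function(e) {
      abort(paste0("Malformed Newick in '", path, "': ", conditionMessage(e)),
            class = "islandpe_parse_error")
    }
  )
  if (is.null(tree)) {
    abort(paste0("Malformed Newick in '", path, "': parser returned nothing"),
          class = "islandpe_parse_error")
  }
  validate_dated_tree(tree)
  if (!quiet) {
    inform(sprintf("Read tree with %d tips and %d edges (total length %.6g)",
                   length(tree$tip.label), nrow(tree$edge),
                   sum(tree$edge.length)))
  }
  tree
}

#' Validate a dated tree
#'
#' Checks the invariants every tree entering the pipeline must satisfy:
#' unique non-empty tip labels, branch lengths present and non-negative on
#' all edges, a single root.
#'
#' @param tree An [ape::phylo] object.
#' @return The tree, invisibly, if valid; otherwise an error.
#' @export
validate_dated_tree <- function(tree) {
  if (!inherits(tree, "phylo")) {
    abort("`tree` must be an ape 'phylo' object", class = "islandpe_validation_error")
  }
  tips <- tree$tip.label
  if (any(is.na(tips)) || any(!nzchar(trimws(tips)))) {
    abort("Tree has empty tip labels", class = "islandpe_validation_error")
  }
  if (anyDuplicated(tips)) {
    dup <- unique(tips[duplicated(tips)])
    abort(paste0("Duplicate tip labels: ", paste(head(dup, 5), collapse = ", ")),
          class = "islandpe_validation_error")
  }
  if (is.null(tree$edge.length)) {
    abort("Tree has no branch lengths", class = "islandpe_validation_error")
  }
  bad <- which(is.na(tree$edge.length) | tree$edge.length < 0)
  if (length(bad)) {
    nodes <- tree$edge[bad, 2]
    abort(paste0("Missing or negative branch length on edge(s) to node(s): ",
                 paste(head(nodes, 5), collapse = ", ")),
          class = "islandpe_validation_error")
  }
  invisible(tree)
}

#' Read occurrence records from a delimited text file
#'
#' Expects a header naming the genus, island, latitude and longitude columns.
#' Rows whose coordinates cannot be parsed or fall outside valid bounds
#' (latitude beyond +/-90, longitude beyond +/-180 after normalization) are
#' dropped and counted; the count is attached as the `rejects` attribute and
#' reported. Longitudes are normalized to [-180, 180].
#'
#' @param path Path to a delimited file.
#' @param delim Field delimiter (default `","`).
#' @param cols Named character vector mapping the canonical names
#'   `genus`, `island_id`, `latitude`, `longitude` (and optionally
#'   `native_flag`) to the column names used in the file.
#' @param quiet Suppress messages.
#' @return A tibble with columns `genus`, `island_id`, `latitude`,
#'   `longitude` (and `native_flag` if mapped), with attribute `rejects`
#'   giving the number of dropped rows.
#' @export
read_occurrences <- function(path,
                             delim = ",",
                             cols = c(genus = "genus", island_id = "island_id",
                                      latitude = "latitude", longitude = "longitude"),
                             quiet = FALSE) {
  if (!file.exists(path)) {
    abort(paste0("Occurrence file not found: ", path), class = "islandpe_io_error")
  }
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           col_types = readr::cols(.default = readr::col_character()),
                           progress = FALSE)
  needed <- c("genus", "island_id", "latitude", "longitude")
  if (!all(needed %in% names(cols))) {
    abort("`cols` must map genus, island_id, latitude and longitude",
          class = "islandpe_config_error")
  }
  missing <- setdiff(unname(cols[needed]), names(raw))
  if (length(missing)) {
    abort(paste0("Missing mandatory column(s) in '", path, "': ",
                 paste(missing, collapse = ", ")),
          class = "islandpe_config_error")
  }
  out <- tibble::tibble(
    genus = trimws(raw[[cols[["genus"]]]]),
    island_id = trimws(raw[[cols[["island_id"]]]]),
    latitude = suppressWarnings(as.numeric(raw[[cols[["latitude"]]]])),
    longitude = suppressWarnings(as.numeric(raw[[cols[["longitude"]]]]))
  )
  if ("native_flag" %in% names(cols) && cols[["native_flag"]] %in% names(raw)) {
    out$native_flag <- raw[[cols[["native_flag"]]]]
  }
  out$longitude <- normalize_longitude(out$longitude)
  ok <- !is.na(out$latitude) & !is.na(out$longitude) &
    out$latitude >= -90 & out$latitude <= 90 &
    out$longitude >= -180 & out$longitude <= 180 &
    nzchar(out$genus)
  rejects <- sum(!ok)
  out <- out[ok, , drop = FALSE]
  if (nrow(out) == 0 && !quiet) {
    warn(paste0("No usable occurrence records in '", path, "'"))
  } else if (!quiet) {
    inform(sprintf("Read %d occurrence records (%d rejected)", nrow(out), rejects))
  }
  attr(out, "rejects") <- rejects
  out
}

#' Normalize longitudes to [-180, 180]
#' @param lon Numeric vector of longitudes (degrees).
#' @return Numeric vector in [-180, 180]; NA passes through.
#' @export
normalize_longitude <- function(lon) {
  out <- ((lon + 180) %% 360) - 180
  # keep +180 as +180 rather than wrapping to -180
  out[!is.na(lon) & lon == 180] <- 180
  out
}

#' Build an island-by-genus incidence matrix
#'
#' Collapses presence-only occurrence records into a binary matrix with
#' islands as rows and genera as columns, keeping only genera that match a
#' tip of the phylogeny exactly (after whitespace trimming; matching is
#' case-sensitive) and islands carrying at least `min_genera` matched genera.
#' Duplicate records collapse silently to a single presence.
#'
#' @param records A data frame with columns `genus` and `island_id`.
#' @param tree An [ape::phylo] whose tip labels are genus names.
#' @param min_genera Minimum number of matched genera an island must carry
#'   to be retained (default 1).
#' @param quiet Suppress the unmatched-genus report.
#' @return A binary integer matrix (islands x genera) with dimnames, rows and
#'   columns sorted by name. Attribute `unmatched` lists genus names absent
#'   from the tree.
#' @export
build_incidence <- function(records, tree, min_genera = 1, quiet = FALSE) {
  stopifnot(is.data.frame(records))
  validate_dated_tree(tree)
  gen <- trimws(as.character(records$genus))
  isl <- trimws(as.character(records$island_id))
  tips <- trimws(tree$tip.label)
  matched <- gen %in% tips
  unmatched <- sort(unique(gen[!matched]))
  if (length(unmatched) && !quiet) {
    warn(sprintf("%d genus name(s) not matched to tree tips: %s",
                 length(unmatched),
                 paste(head(unmatched, 10), collapse = ", ")))
  }
  gen <- gen[matched]
  isl <- isl[matched]
  if (!length(gen)) {
    abort("No occurrence genus matched a tree tip", class = "islandpe_data_error")
  }
  genera <- sort(unique(gen))
  islands <- sort(unique(isl))
  m <- matrix(0L, length(islands), length(genera),
              dimnames = list(islands, genera))
  m[cbind(match(isl, islands), match(gen, genera))] <- 1L
  keep <- rowSums(m) >= min_genera
  m <- m[keep, , drop = FALSE]
  if (nrow(m) == 0) {
    abort("No island retains the minimum number of matched genera",
          class = "islandpe_data_error")
  }
  attr(m, "unmatched") <- unmatched
  m
}

#' Validate an incidence matrix
#'
#' @param incidence Binary matrix, islands as rows, genera as columns, with
#'   dimnames.
#' @return The matrix, invisibly.
#' @export
validate_incidence <- function(incidence) {
  if (!is.matrix(incidence) || is.null(rownames(incidence)) ||
      is.null(colnames(incidence))) {
    abort("`incidence` must be a matrix with island rownames and genus colnames",
          class = "islandpe_validation_error")
  }
  if (!all(incidence %in% c(0L, 1L))) {
    abort("`incidence` entries must be 0/1", class = "islandpe_validation_error")
  }
  invisible(incidence)
}

#' Write the per-island results table
#'
#' Joins scores, tail frequencies and category assignments on
#' (`island_id`, `variant`) and writes one tab-separated row per island with
#' columns `island_id`, `variant`, `PE`, `PEalt`, `RPE`, `freq_PE`,
#' `freq_PEalt_high`, `freq_RPE_high`, `freq_RPE_low`, `category`, sorted by
#' island id then variant. Floats are serialized with 12 significant digits.
#'
#' @param scores Tibble from [endemism_scores()].
#' @param frequencies Tibble from [tail_frequencies()].
#' @param categories Tibble from [assign_categories()].
#' @param path Output file path (TSV, UTF-8).
#' @return The written tibble, invisibly.
#' @export
write_results <- function(scores, frequencies, categories, path) {
  key_s <- paste(scores$island_id, scores$variant)
  key_f <- paste(frequencies$island_id, frequencies$variant)
  key_c <- paste(categories$island_id, categories$variant)
  off <- c(setdiff(key_s, key_f), setdiff(key_f, key_s), setdiff(key_s, key_c))
  if (length(off)) {
    abort(paste0("Misaligned island ids across results tables: ",
                 paste(head(unique(off), 10), collapse = ", ")),
          class = "islandpe_data_error")
  }
  out <- scores |>
    dplyr::inner_join(
      dplyr::select(frequencies, "island_id", "variant",
                    freq_PE = "freq_higher_pe",
                    freq_PEalt_high = "freq_higher_pe_alt",
                    freq_RPE_high = "freq_higher_rpe",
                    freq_RPE_low = "freq_lower_rpe"),
      by = c("island_id", "variant")
    ) |>
    dplyr::inner_join(
      dplyr::select(categories, "island_id", "variant", "category"),
      by = c("island_id", "variant")
    ) |>
    dplyr::select("island_id", "variant",
                  PE = "pe", PEalt = "pe_alt", RPE = "rpe",
                  "freq_PE", "freq_PEalt_high", "freq_RPE_high",
                  "freq_RPE_low", "category") |>
    dplyr::arrange(.data$island_id, .data$variant)
  if (nrow(out) == 0) warn("Writing header-only results table")
  fmt <- out |>
    dplyr::mutate(dplyr::across(dplyr::where(is.numeric),
                                ~ formatC(.x, digits = 12, format = "g")))
  readr::write_tsv(fmt, path)
  invisible(out)
}
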