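#' Branch-by-tip structure of a tree
#'
#' Internal workhorse: for every edge of the tree, which tips descend from
#' it. Computed once per tree and reused across the observed matrix and all
#' null randomizations. The root edge (a `root.edge` element, if the Newick
#' carried one) is not part of the edge matrix and is ignored throughout: it
#' would sit on every island's root path and add only a constant.
#'
#' @param tree An [ape::phylo].
#' @return A list with `desc` (logical edges x tips matrix), `lengths`
#'   (edge lengths, My), `tip_labels`.
#' @keywords internal
branch_structure <- function(tree) {
  validate_dated_tree(tree)
  nt <- length(tree$tip.label)
  edge <- tree$edge
  ne <- nrow(edge)
  desc <- matrix(FALSE, ne, nt)
  # postorder: children are resolved before their parent edge
  po <- ape::reorder.phylo(tree, "postorder")
  ord <- match(paste(po$edge[, 1], po$edge[, 2]), paste(edge[, 1], edge[, 2]))
  node_rows <- split(seq_len(ne), edge[, 1]) # outgoing edges per node
  for (k in seq_len(ne)) {
    e <- ord[k]
    child <- edge[e, 2]
    if (child <= nt) {
      desc[e, child] <- TRUE
    } else {
      for (ce in node_rows[[as.character(child)]]) {
        desc[e, ] <- desc[e, ] | desc[ce, ]
      }
    }
  }
  list(desc = desc, lengths = tree$edge.length, tip_labels = trimws(tree$tip.label))
}

#' Align an incidence matrix with a tree's tips
#'
#' @return Integer matrix islands x tips (tree tip order), zero-filled for
#'   tips absent from the incidence matrix.
#' @keywords internal
align_incidence <- function(incidence, struct) {
  validate_incidence(incidence)
  genera <- trimws(colnames(incidence))
  hit <- match(struct$tip_labels, genera)
  x <- matrix(0L, nrow(incidence), length(struct$tip_labels),
              dimnames = list(rownames(incidence), struct$tip_labels))
  found <- !is.na(hit)
  x[, found] <- incidence[, hit[found], drop = FALSE]
  x
}

#' Per-branch island ranges
#'
#' For every branch of the tree, the set of islands harboring at least one
#' descendant genus and its size `R_c`. Under the restricted variant, any
#' branch supporting a continent-occurring genus (terminal or internal, with
#' at least one continental descendant) has its range set wholesale to
#' `n_max`, the maximum number of islands a genus could occupy, so that
#' continental lineages carry almost no weight.
#'
#' @param tree An [ape::phylo] with genus tips.
#' @param incidence Binary islands x genera matrix (see [build_incidence()]).
#' @param annotations For `variant = "restricted"`, a data frame with columns
#'   `genus` and `continental` (logical).
#' @param variant `"expanded"` (default) or `"restricted"`.
#' @param n_max Denominator used for continental branches under the
#'   restricted variant; defaults to the number of islands in `incidence`.
#' @param terminal_only If `TRUE`, the restricted rule is applied only to
#'   terminal branches of continental genera, not to internal branches with a
#'   mixed set of descendants (default `FALSE`).
#' @return A tibble with one row per branch: `branch`, `length`, `r_c`,
#'   `continental_support`, `r_used` (the denominator actually used), plus a
#'   `presence` attribute (logical branches x islands matrix).
#' @export
branch_ranges <- function(tree, incidence, annotations = NULL,
                          variant = c("expanded", "restricted"),
                          n_max = NULL, terminal_only = FALSE) {
  variant <- match.arg(variant)
  struct <- branch_structure(tree)
  ranges_from_struct(struct, incidence, annotations, variant, n_max,
                     terminal_only)
}

# internal version taking a precomputed branch structure (hot path under the
# null model)
ranges_from_struct <- function(struct, incidence, annotations, variant,
                               n_max = NULL, terminal_only = FALSE) {
  x <- align_incidence(incidence, struct)
  n_islands <- nrow(x)
  if (is.null(n_max)) n_max <- n_islands
  # branches x islands presence: branch c present on island i iff any
  # descendant tip of c occurs on i
  pres <- tcrossprod(struct$desc, x) > 0
  r_c <- as.integer(rowSums(pres))
  cont <- rep(FALSE, nrow(struct$desc))
  if (variant == "restricted") {
    if (is.null(annotations) || !all(c("genus", "continental") %in% names(annotations))) {
      abort("restricted variant needs `annotations` with columns genus, continental",
            class = "islandpe_config_error")
    }
    if (n_max < n_islands) {
      abort("`n_max` must be at least the number of islands",
            class = "islandpe_config_error")
    }
    flag <- rep(FALSE, length(struct$tip_labels))
    hit <- match(trimws(as.character(annotations$genus)), struct$tip_labels)
    flag[hit[!is.na(hit)]] <- as.logical(annotations$continental)[!is.na(hit)]
    cont <- as.vector(struct$desc %*% flag > 0)
    if (terminal_only) {
      cont <- cont & rowSums(struct$desc) == 1
    }
  }
  r_used <- r_c
  r_used[cont & r_c > 0] <- as.integer(n_max)
  out <- tibble::tibble(
    branch = seq_along(r_c),
    length = struct$lengths,
    r_c = r_c,
    continental_support = as.vector(cont),
    r_used = r_used
  )
  attr(out, "presence") <- pres
  attr(out, "n_islands") <- n_islands
  attr(out, "island_ids") <- rownames(incidence)
  out
}

# shared summation: per-island sum of weight_c over branches present there
.sum_over_islands <- function(ranges, weights) {
  pres <- attr(ranges, "presence")
  w <- ifelse(ranges$r_used > 0, weights / ranges$r_used, 0)
  as.vector(crossprod(pres, w))
}

#' Per-island phylogenetic endemism
#'
#' PE(i) is the sum, over the branches joining island i's genera to the root,
#' of branch length divided by the number of islands on which the branch is
#' present (its island range `R_c`; `n_max` for continental branches under
#' the restricted variant). On an island holding every branch alone
#' (all `R_c = 1`) PE reduces to Faith's phylogenetic diversity.
#'
#' @param ranges Output of [branch_ranges()].
#' @return Tibble with `island_id` and `pe` (My).
#' @export
pe_scores <- function(ranges) {
  tibble::tibble(
    island_id = attr(ranges, "island_ids"),
    pe = .sum_over_islands(ranges, ranges$length)
  )
}

#' Per-island PE under uniform branch lengths
#'
#' Same summation as [pe_scores()] but with every branch length replaced by a
#' single value, by default the arithmetic mean of all branch lengths of the
#' original tree. This keeps the topology and range structure while removing
#' branch-length variation, so the PE/PEalt ratio isolates whether rare
#' branches on an island are unusually long or short.
#'
#' @param ranges Output of [branch_ranges()].
#' @param l_uniform Uniform branch length (My); default mean of the tree's
#'   branch lengths. Must be positive.
#' @return Tibble with `island_id` and `pe_alt`.
#' @export
pe_alt_scores <- function(ranges, l_uniform = NULL) {
  if (is.null(l_uniform)) l_uniform <- mean(ranges$length)
  if (!is.numeric(l_uniform) || length(l_uniform) != 1 || l_uniform <= 0) {
    abort("`l_uniform` must be a single positive number",
          class = "islandpe_config_error")
  }
  tibble::tibble(
    island_id = attr(ranges, "island_ids"),
    pe_alt = .sum_over_islands(ranges, rep(l_uniform, nrow(ranges)))
  )
}

#' Per-island endemism scores (PE, PEalt, RPE)
#'
#' Convenience wrapper computing the three metrics for one variant. Islands
#' with no genera (possible only if the incidence matrix was built with
#' `min_genera = 0`) get PE = 0 and an undefined (NA) RPE.
#'
#' @inheritParams branch_ranges
#' @param l_uniform Uniform branch length for PEalt; default mean branch
#'   length of `tree`.
#' @return Tibble with columns `island_id`, `variant`, `richness`, `pe`,
#'   `pe_alt`, `rpe`, and attribute `l_uniform`.
#' @export
#' @examples
#' tr <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
#' m <- matrix(c(1,1,0, 0,1,0, 0,1,1), nrow = 3, byrow = TRUE,
#'             dimnames = list(c("I1","I2","I3"), c("A","B","C")))
#' endemism_scores(tr, m)
endemism_scores <- function(tree, incidence, annotations = NULL,
                            variant = c("expanded", "restricted"),
                            n_max = NULL, l_uniform = NULL,
                            terminal_only = FALSE) {
  variant <- match.arg(variant)
  ranges <- branch_ranges(tree, incidence, annotations, variant, n_max,
                          terminal_only)
  if (is.null(l_uniform)) l_uniform <- mean(ranges$length)
  scores_from_ranges(ranges, incidence, variant, l_uniform)
}

scores_from_ranges <- function(ranges, incidence, variant, l_uniform) {
  pe_tab <- pe_scores(ranges)
  alt_tab <- pe_alt_scores(ranges, l_uniform)
  out <- tibble::tibble(
    island_id = pe_tab$island_id,
    variant = variant,
    richness = as.integer(rowSums(incidence)),
    pe = pe_tab$pe,
    pe_alt = alt_tab$pe_alt,
    rpe = ifelse(alt_tab$pe_alt > 0, pe_tab$pe / alt_tab$pe_alt, NA_real_)
  )
  attr(out, "l_uniform") <- l_uniform
  out
}

#' Islands eligible for the restricted-variant test
#'
#' The restricted analysis is only meaningful on islands harboring at least
#' one island-specific genus (one with no recorded continental occurrence);
#' islands whose genera all occur on continents are excluded so they cannot
#' be falsely identified as areas of restricted endemism.
#'
#' @param incidence Binary islands x genera matrix.
#' @param annotations Data frame with columns `genus`, `continental`.
#' @return Character vector of retained island ids.
#' @export
restrict_islands <- function(incidence, annotations) {
  validate_incidence(incidence)
  flag <- annotations$continental[match(trimws(colnames(incidence)),
                                        trimws(as.character(annotations$genus)))]
  flag[is.na(flag)] <- FALSE # unflagged genera treated as island-restricted
  insular <- incidence[, !flag, drop = FALSE]
  rownames(incidence)[rowSums(insular) > 0]
}
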