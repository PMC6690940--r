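# Shared fixtures and independent oracles.

toy_tree <- function() ape::read.tree(text = "((A:1,B:1):1,C:2);")

# I1 = {A}, I2 = {A,B,C}, I3 = {C}
toy_incidence <- function() {
  matrix(c(1L, 1L, 0L, 0L, 1L, 0L, 0L, 1L, 1L), nrow = 3,
         dimnames = list(c("I1", "I2", "I3"), c("A", "B", "C")))
}

toy_annotations <- function() {
  tibble::tibble(genus = c("A", "B", "C"),
                 continental = c(FALSE, FALSE, TRUE))
}

# Brute-force PE/PEalt/RPE: for each island, enumerate the path edges from
# every present tip up to the root, recompute each edge's island range from
# scratch, and sum. Deliberately naive and independent of branch_structure().
oracle_pe_scores <- function(tree, m, annotations = NULL,
                             variant = "expanded", n_max = nrow(m),
                             l_uniform = NULL) {
  nt <- length(tree$tip.label)
  edge <- tree$edge
  if (is.null(l_uniform)) l_uniform <- mean(tree$edge.length)
  tips_of_edge <- function(e) {
    ch <- edge[e, 2]
    if (ch <= nt) return(tree$tip.label[ch])
    unlist(lapply(which(edge[, 1] == ch), tips_of_edge))
  }
  cont <- setNames(rep(FALSE, nt), tree$tip.label)
  if (!is.null(annotations)) {
    cont[as.character(annotations$genus)] <- as.logical(annotations$continental)
  }
  res <- data.frame(island_id = rownames(m), pe = 0, pe_alt = 0)
  for (i in seq_len(nrow(m))) {
    present <- colnames(m)[m[i, ] == 1]
    path_edges <- integer()
    for (g in present) {
      node <- match(g, tree$tip.label)
      repeat {
        e <- which(edge[, 2] == node)
        if (!length(e)) break
        path_edges <- c(path_edges, e)
        node <- edge[e, 1]
      }
    }
    for (e in unique(path_edges)) {
      tps <- intersect(tips_of_edge(e), colnames(m))
      r <- sum(rowSums(m[, tps, drop = FALSE]) > 0)
      r_used <- if (variant == "restricted" && any(cont[tips_of_edge(e)])) n_max else r
      res$pe[i] <- res$pe[i] + tree$edge.length[e] / r_used
      res$pe_alt[i] <- res$pe_alt[i] + l_uniform / r_used
    }
  }
  res$rpe <- ifelse(res$pe_alt > 0, res$pe / res$pe_alt, NA_real_)
  res
}

# Exhaustive enumeration of the fixed-marginal fiber of a small binary matrix.
enumerate_fiber <- function(m) {
  n <- length(m)
  combos <- as.matrix(expand.grid(rep(list(0:1), n)))
  rs <- rowSums(m)
  cs <- colSums(m)
  out <- list()
  for (i in seq_len(nrow(combos))) {
    x <- matrix(as.integer(combos[i, ]), nrow(m), ncol(m),
                dimnames = dimnames(m))
    if (all(rowSums(x) == rs) && all(colSums(x) == cs)) out[[length(out) + 1]] <- x
  }
  out
}

# Random small fixture: tree plus incidence with every genus on >= 1 island.
random_fixture <- function(seed, n_genera = 12, n_islands = 6) {
  set.seed(seed)
  tree <- ape::rtree(n_genera)
  tree$tip.label <- sprintf("g%02d", seq_len(n_genera))
  m <- matrix(0L, n_islands, n_genera,
              dimnames = list(sprintf("i%02d", seq_len(n_islands)),
                              tree$tip.label))
  for (g in seq_len(n_genera)) {
    k <- sample.int(n_islands, 1)
    m[sample.int(n_islands, k), g] <- 1L
  }
  list(tree = tree, incidence = m)
}
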