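test_that("generation is byte-identical given the scenario seed", {
  sc <- endemism_scenario(n_genera = 40, n_islands = 20, seed = 5,
                          f_paleo = 0.2, f_neo = 0.2,
                          paleo_islands = 1:2, neo_islands = 3:4)
  a <- synthesize_dataset(sc, with_records = TRUE,
                          out_of_box_fraction = 0.05,
                          non_native_fraction = 0.05)
  b <- synthesize_dataset(sc, with_records = TRUE,
                          out_of_box_fraction = 0.05,
                          non_native_fraction = 0.05)
  expect_identical(ape::write.tree(a$tree), ape::write.tree(b$tree))
  expect_identical(a$incidence, b$incidence)
  expect_identical(a$records, b$records)
  # a different seed changes the world
  c2 <- synthesize_dataset(endemism_scenario(n_genera = 40, n_islands = 20,
                                             seed = 6))
  expect_false(identical(ape::write.tree(a$tree), ape::write.tree(c2$tree)))
})

test_that("pool tips carry scaled terminal branches", {
  recalls <- sapply(1:20, function(s) {
    sc <- endemism_scenario(n_genera = 60, n_islands = 30, seed = s,
                            f_paleo = 0.1, f_neo = 0.1, m_long = 5)
    tr <- generate_tree(sc)
    pools <- attr(tr, "pools")
    term <- tr$edge.length[match(seq_along(tr$tip.label), tr$edge[, 2])]
    mean(term[pools$pool == "paleo"]) / mean(term[pools$pool == "background"])
  })
  # with multiplier 5, paleo terminal branches average >= 3x background
  expect_gte(mean(recalls), 3)

  # f_paleo = f_neo = 0 leaves an ordinary pure-birth tree
  sc0 <- endemism_scenario(n_genera = 30, n_islands = 10, seed = 1,
                           f_paleo = 0, f_neo = 0)
  tr0 <- generate_tree(sc0)
  expect_true(all(attr(tr0, "pools")$pool == "background"))
  expect_true(ape::is.ultrametric(tr0, tol = 1e-6))
})

test_that("incidence satisfies its invariants and the occupancy model is right-skewed", {
  frac_rare <- sapply(1:5, function(s) {
    sc <- endemism_scenario(n_genera = 300, n_islands = 100, seed = s,
                            occupancy_exponent = 2)
    d <- synthesize_dataset(sc)
    expect_true(all(d$incidence %in% c(0L, 1L)))
    expect_true(all(rowSums(d$incidence) >= 1))  # no empty islands
    expect_true(all(colSums(d$incidence) >= 1))  # every genus somewhere
    mean(colSums(d$incidence) <= 2)
  })
  expect_true(all(frac_rare >= 0.5))
})

test_that("continental flags hit the requested fraction of genera", {
  sc <- endemism_scenario(n_genera = 300, n_islands = 80, seed = 9,
                          continental_fraction = 0.3)
  d <- synthesize_dataset(sc)
  p <- mean(d$annotations$continental)
  expect_lt(abs(p - 0.3), 3 * sqrt(0.3 * 0.7 / 300))
  # flags only on non-pool genera
  expect_false(any(d$annotations$continental & d$annotations$pool != "background"))
})

test_that("infeasible planting raises a generation error", {
  sc <- endemism_scenario(n_genera = 30, n_islands = 20, seed = 1,
                          f_paleo = 0.05, paleo_islands = 1:10,
                          genera_per_planted = 3)
  tr <- generate_tree(sc)
  expect_error(generate_incidence(sc, tr), class = "islandpe_generation_error")
})

test_that("noise-free records recover the incidence; filters remove exactly the noise", {
  sc <- endemism_scenario(n_genera = 80, n_islands = 30, seed = 12)
  d <- synthesize_dataset(sc, with_records = TRUE,
                          out_of_box_fraction = 0.1,
                          non_native_fraction = 0.05)
  rec <- d$records

  # bounding-box filter removes exactly the out-of-box noise
  kept <- filter_bounding_box(rec[rec$noise != "non_native", ],
                              d$annotations, quiet = TRUE)
  expect_false(any(kept$noise == "out_of_box"))
  expect_equal(sum(rec$noise == "none"), sum(kept$noise == "none"))

  # native-status filter removes exactly the flagged noise
  kept2 <- filter_native_status(rec[rec$noise != "out_of_box", ],
                                d$island_regions, d$native_status,
                                quiet = TRUE)
  expect_false(any(kept2$noise == "non_native"))
  expect_equal(sum(rec$noise == "none"), sum(kept2$noise == "none"))

  # both filters + dedup recover the clean incidence exactly
  clean <- filter_native_status(
    filter_bounding_box(rec, d$annotations, quiet = TRUE),
    d$island_regions, d$native_status, quiet = TRUE)
  m <- build_incidence(clean, d$tree, quiet = TRUE)
  keep_rows <- rownames(d$incidence) %in% rownames(m)
  expect_equal(m[rownames(d$incidence)[keep_rows], colnames(d$incidence)],
               d$incidence[keep_rows, ], ignore_attr = TRUE)
  expect_true(all(keep_rows))

  # zero noise fractions make the filters no-ops
  d0 <- synthesize_dataset(sc, with_records = TRUE)
  k0 <- filter_bounding_box(d0$records, d0$annotations, quiet = TRUE)
  expect_equal(nrow(k0), nrow(d0$records))
})

test_that("recovery_report computes recall and false positives from planted truth", {
  sc <- endemism_scenario(n_genera = 40, n_islands = 10, seed = 2,
                          paleo_islands = 1:2, neo_islands = 3:4)
  asg <- tibble::tibble(
    island_id = sprintf("I%04d", 1:10),
    category = factor(c("paleo", "not_significant", "neo", "neo",
                        rep("not_significant", 5), "mixed"),
                      levels = islandpe:::ENDEMISM_CATEGORIES)
  )
  rep <- recovery_report(asg, sc)
  expect_equal(rep$summary$recall[rep$summary$class == "paleo"], 0.5)
  expect_equal(rep$summary$recall[rep$summary$class == "neo"], 1.0)
  expect_equal(rep$false_positive_rate, 1 / 6)
})

test_that("planted recall is monotone in kappa (paired seeds, small worlds)", {
  recall_at <- function(kappa, seed) {
    sc <- endemism_scenario(n_genera = 120, n_islands = 40, seed = seed,
                            f_paleo = 0.3, f_neo = 0.3,
                            m_long = 10, m_short = 0.1,
                            occupancy_exponent = 1.2,
                            pool_max_islands = 1,
                            paleo_islands = 1:2, neo_islands = 3:4,
                            kappa = kappa, genera_per_planted = 9)
    d <- synthesize_dataset(sc)
    res <- run_endemism(d$tree, d$incidence, d$annotations,
                        variants = "expanded", n_sims = 200, seed = seed)
    rep <- recovery_report(res$assignments, sc)
    mean(rep$summary$recall)
  }
  seeds <- 1:3
  r0 <- mean(sapply(seeds, function(s) recall_at(0, s)))
  r5 <- mean(sapply(seeds, function(s) recall_at(0.5, s)))
  r1 <- mean(sapply(seeds, function(s) recall_at(1, s)))
  expect_lte(r0, r5)
  expect_lte(r5, r1)
  expect_gt(r1, 0.5)
})
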