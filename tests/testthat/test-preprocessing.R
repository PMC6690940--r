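make_records <- function() {
  tibble::tibble(
    genus = c("Aa", "Aa", "Bb", "Cc"),
    island_id = c("I1", "I2", "I1", "I3"),
    latitude = c(0, 25, 5, 0),
    longitude = c(120, 120, 110, 179)
  )
}

test_that("native-status filter removes non-native, passes unknown", {
  rec <- make_records()
  regions <- tibble::tibble(island_id = c("I1", "I2", "I3"),
                            region_id = c("R1", "R2", "R3"))
  status <- tibble::tibble(
    genus = c("Aa", "Aa", "Bb"),
    region_id = c("R1", "R2", "R1"),
    status = c("native", "non_native", "unknown")
  )
  out <- filter_native_status(rec, regions, status, quiet = TRUE)
  expect_equal(nrow(out), 3)
  expect_false(any(out$genus == "Aa" & out$island_id == "I2"))
  rep <- attr(out, "filter_report")
  expect_equal(rep$removed, 1)
  expect_equal(rep$untested, 2) # Bb unknown, Cc no entry

  # island without region mapping passes with warning
  regions2 <- regions[regions$island_id != "I3", ]
  expect_warning(out2 <- filter_native_status(rec, regions2, status),
                 "no region mapping")
  expect_true("I3" %in% out2$island_id)

  # idempotent
  out3 <- filter_native_status(out, regions, status, quiet = TRUE)
  expect_equal(out3$genus, out$genus)
})

test_that("bounding-box filter is boundary-inclusive and handles the antimeridian", {
  ann <- tibble::tibble(genus = "Aa", lat_min = -10, lat_max = 10,
                        lon_min = 100, lon_max = 140)
  rec <- tibble::tibble(genus = "Aa", island_id = "I1",
                        latitude = c(0, 25, 10, 0),
                        longitude = c(120, 120, 140, 141))
  out <- filter_bounding_box(rec, ann, quiet = TRUE)
  expect_equal(nrow(out), 2) # interior point and both-boundaries point stay
  expect_true(all(out$latitude <= 10 & out$longitude <= 140))

  # box crossing the antimeridian: lon in [170, 180] U [-180, -160]
  ann2 <- tibble::tibble(genus = "Zz", lat_min = -10, lat_max = 10,
                         lon_min = 170, lon_max = -160)
  rec2 <- tibble::tibble(genus = "Zz", island_id = "I1",
                         latitude = 0, longitude = c(179, -170, 0, 170, -160))
  out2 <- filter_bounding_box(rec2, ann2, quiet = TRUE)
  expect_equal(out2$longitude, c(179, -170, 170, -160))

  # genus without a box passes with a warning
  rec3 <- tibble::tibble(genus = "Qq", island_id = "I1",
                         latitude = 89, longitude = 0)
  expect_warning(out3 <- filter_bounding_box(rec3, ann), "without a bounding box")
  expect_equal(nrow(out3), 1)

  # inverted latitude box is a configuration error
  bad <- tibble::tibble(genus = "Aa", lat_min = 10, lat_max = -10,
                        lon_min = 0, lon_max = 10)
  expect_error(filter_bounding_box(rec, bad, quiet = TRUE),
               class = "islandpe_config_error")

  # idempotent
  expect_equal(nrow(filter_bounding_box(out, ann, quiet = TRUE)), nrow(out))
})

test_that("species-area model recovers a noiseless power law exactly", {
  tab <- generate_island_table(50, seed = 2, intercept = 3, exponent = 0.25,
                               sigma = 0)
  fit <- fit_richness_model(tab)
  expect_equal(unname(coef(fit$fit)[2]), 0.25, tolerance = 1e-9)
  expect_equal(unname(coef(fit$fit)[1]), log10(3), tolerance = 1e-9)
  expect_equal(predict_richness(fit, tab), tab$richness, tolerance = 1e-6)
  # summary.lm warns on the numerically perfect fit; the values are the point
  td <- suppressWarnings(tidy(fit))
  expect_equal(td$estimate[2], 0.25, tolerance = 1e-9)
  expect_false(suppressWarnings(glance(fit))$unreliable)
})

test_that("species-area slope is recovered under lognormal noise", {
  tab <- generate_island_table(200, seed = 7, sigma = 0.1)
  fit <- fit_richness_model(tab)
  expect_lt(abs(coef(fit$fit)[2] - 0.25), 0.05)
})

test_that("degenerate and tiny richness designs are handled", {
  tab <- tibble::tibble(island_id = c("a", "b", "c"),
                        richness = c(5, 5, 5), area = c(10, 10, 10))
  expect_error(fit_richness_model(tab), class = "islandpe_data_error")
  tab2 <- tibble::tibble(island_id = c("a", "b"),
                         richness = c(3, 30), area = c(10, 10000))
  expect_warning(fit2 <- fit_richness_model(tab2), "unreliable")
  expect_true(fit2$unreliable)
})

test_that("under-sampling exclusion applies the observed < predicted/factor rule", {
  # boundary arithmetic: predicted 49, factor 5 -> threshold 9.8
  pred <- c(49, 49, 49)
  obs <- c(10, 9, 49)
  excluded <- obs < pred / 5
  expect_equal(excluded, c(FALSE, TRUE, FALSE)) # 10 kept, 9 dropped, 49 kept

  # via the real interface: power-law world where prediction is exact
  tab3 <- generate_island_table(30, seed = 3, sigma = 0)
  fit <- fit_richness_model(tab3)
  tab3$richness[5] <- predict_richness(fit, tab3[5, ]) / 5 - 1e-9 # just below
  tab3$richness[6] <- predict_richness(fit, tab3[6, ]) / 5       # exactly at
  res <- exclude_undersampled(tab3, fit, factor = 5)
  expect_true(tab3$island_id[5] %in% res$report$island_id)
  expect_false(tab3$island_id[6] %in% res$report$island_id)
  expect_error(exclude_undersampled(tab3, fit, factor = 1),
               class = "islandpe_config_error")
})

test_that("exclusion is monotone in the factor", {
  tab <- generate_island_table(100, seed = 11, sigma = 0.4)
  fit <- fit_richness_model(tab)
  kept <- lapply(c(2, 5, 10), function(f)
    exclude_undersampled(tab, fit, factor = f)$retained)
  expect_true(all(kept[[1]] %in% kept[[2]]))
  expect_true(all(kept[[2]] %in% kept[[3]]))
})

test_that("ICE coverage matches an independently coded closed form", {
  # fixture: Q1 = 3, Q2 = 2, five infrequent taxa over 4 units
  d <- tibble::tibble(island_id = "I1",
                      taxon = paste0("t", 1:6),
                      n_units = c(1, 1, 1, 2, 2, 12))
  units <- tibble::tibble(island_id = "I1", n_units_total = 4)
  got <- ice_coverage(d, units)
  # independent evaluation of the formula
  q1 <- 3; q2 <- 2; s_inf <- 5; s_freq <- 1; m <- 4
  n_inf <- 1 + 1 + 1 + 2 + 2
  c_ice <- 1 - q1 / n_inf
  g2 <- max(s_inf / c_ice * m / (m - 1) * (2 * 1 * q2) / n_inf^2 - 1, 0)
  s_ice <- s_freq + s_inf / c_ice + q1 * g2 / c_ice
  expect_equal(got$s_ice, s_ice, tolerance = 1e-12)
  expect_equal(got$icer, 6 / s_ice, tolerance = 1e-12)
  expect_equal(got$flag, "ok")
})

test_that("ICE degenerate inputs follow the documented contracts", {
  # all taxa frequent -> ICEr = 1
  d <- tibble::tibble(island_id = "I1", taxon = paste0("t", 1:3),
                      n_units = c(11, 12, 20))
  got <- ice_coverage(d)
  expect_equal(got$icer, 1)
  # single singleton taxon -> C_ice = 0 -> Chao2-style guard, flagged unstable
  d2 <- tibble::tibble(island_id = "I2", taxon = "t1", n_units = 1)
  got2 <- ice_coverage(d2)
  expect_equal(got2$flag, "unstable")
  expect_true(got2$icer > 0 && got2$icer <= 1)
  # zero sampling units -> undefined
  d3 <- tibble::tibble(island_id = "I3", taxon = "t1", n_units = 0)
  expect_equal(ice_coverage(d3)$flag, "undefined")
})

test_that("ICEr stays in (0,1] and decreases as singletons are added", {
  base <- tibble::tibble(island_id = "I1", taxon = paste0("t", 1:8),
                         n_units = c(1, 2, 3, 4, 5, 6, 12, 15))
  units <- tibble::tibble(island_id = "I1", n_units_total = 20)
  g0 <- ice_coverage(base, units)
  expect_true(g0$icer > 0 && g0$icer <= 1)
  more <- dplyr::bind_rows(base,
                           tibble::tibble(island_id = "I1",
                                          taxon = paste0("s", 1:3),
                                          n_units = 1))
  g1 <- ice_coverage(more, units)
  expect_lte(g1$icer, g0$icer + 1e-12)
})
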