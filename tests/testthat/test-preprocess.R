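test_that("tarsus conversion applies per-method linear calibrations", {
  expect_equal(convert_tarsus(19.5, "svensson_alternative"), 19.5)
  expect_equal(convert_tarsus(20.0, "maxilla",
                              list(maxilla = c(1.05, -0.8))), 20.2)
  expect_error(convert_tarsus(20.0, "unknown_calipers"), "calibration")
})

test_that("outlier windows retain exactly the closed interval", {
  obs <- data.frame(value = c(26.0, 20.0, 12.70, 25.49, 12.69))
  out <- filter_outliers(obs, "great_tit", "adult_tarsus")
  expect_equal(out$obs$value, c(20.0, 12.70, 25.49))
  expect_equal(out$report$rows_removed, 2)

  bt <- filter_outliers(data.frame(value = c(21.5, 20.9)),
                        "blue_tit", "nestling_tarsus")
  expect_equal(bt$obs$value, 20.9)

  ok <- filter_outliers(data.frame(value = c(15, 18, 20)),
                        "great_tit", "adult_tarsus")
  expect_equal(ok$report$rows_removed, 0)

  expect_error(filter_outliers(obs, "great_tit", "wing_length"),
               "window")
})

test_that("first-clutch selection keeps the 30-day window per group", {
  obs <- data.frame(individual_id = c("f1", "f2", "f3"),
                    species = "great_tit", year = 2015,
                    cluster_id = "c1", value = c(100, 115, 135))
  out <- select_first_clutches(obs)
  expect_equal(sort(out$obs$value), c(100, 115))
  expect_equal(out$report$rows_removed, 1)

  single <- select_first_clutches(obs[2, ])
  expect_equal(single$obs$value, 115)

  # a female with two clutches in one season keeps the earlier one
  rep2 <- data.frame(individual_id = "f1", species = "great_tit",
                     year = 2015, cluster_id = "c1", value = c(100, 120))
  expect_equal(select_first_clutches(rep2)$obs$value, 100)

  expect_error(select_first_clutches(obs[, -4]), "cluster_id")
})

test_that("deduplication follows the trait-specific rule", {
  ad <- data.frame(individual_id = c("a", "a", "b"),
                   year = c(2011, 2013, 2011),
                   value = c(19.0, 19.4, 17.0))
  out <- dedupe_individuals(ad, "adult_tarsus")
  expect_equal(out$obs$value[out$obs$individual_id == "a"], 19.2)
  expect_equal(nrow(out$obs), 2)

  ne <- data.frame(individual_id = sprintf("n%d", 1:8),
                   brood_id = c(rep("br1", 6), "br2", "br3"),
                   year = 2012, value = rnorm(8, 16))
  s1 <- dedupe_individuals(ne, "nestling_tarsus", seed = 5)
  s2 <- dedupe_individuals(ne, "nestling_tarsus", seed = 5)
  expect_equal(s1$obs, s2$obs)
  expect_equal(nrow(s1$obs), 3)  # one per brood
  picks <- vapply(1:20, function(s)
    dedupe_individuals(ne, "nestling_tarsus", seed = s)$obs$individual_id[1],
    character(1))
  expect_gt(length(unique(picks)), 1)  # different seeds can differ

  ne_bad <- ne; ne_bad$brood_id[2] <- NA
  expect_error(dedupe_individuals(ne_bad, "nestling_tarsus"), "brood_id")

  ld <- data.frame(individual_id = c("f", "f"), year = c(2017, 2015),
                   value = c(110, 120))
  out_ld <- dedupe_individuals(ld, "lay_date")
  expect_equal(out_ld$obs$year, 2015)
})

test_that("nestling selection does not disturb the global RNG stream", {
  ne <- data.frame(individual_id = sprintf("n%d", 1:6),
                   brood_id = rep("br1", 6), year = 2012, value = rnorm(6))
  set.seed(123)
  before <- runif(1)
  set.seed(123)
  invisible(dedupe_individuals(ne, "nestling_tarsus", seed = 99))
  expect_equal(runif(1), before)
})

test_that("standardize is exact and invertible", {
  st <- standardize(c(1, 2, 3))
  expect_equal(st$z, c(-1, 0, 1))
  expect_error(standardize(rep(5, 4), "shannon_h"), "shannon_h")

  set.seed(1)
  x <- rnorm(100, 50, 7)
  st2 <- standardize(x)
  expect_equal(mean(st2$z), 0, tolerance = 1e-10)
  expect_equal(sd(st2$z), 1, tolerance = 1e-10)
  expect_equal(unstandardize(st2$z, st2$center, st2$scale), x,
               tolerance = 1e-10)
})

test_that("the filter chain is fully audited", {
  scn <- sim_scenario(n_systems = 1, clusters_per_habitat = 2,
                      obs_per_cluster_year = 5, years = 2)
  sim <- simulate_observations(scn, seed = 21, units = "original")
  obs <- sim$obs[setdiff(names(sim$obs), "cluster_id")]
  # contaminate with an out-of-window value and a foreign species row
  obs$value[1] <- 99
  extra <- obs[2, ]; extra$species <- "blue_tit"
  obs <- rbind(obs, extra)
  pp <- suppressMessages(
    preprocess_trait(obs, sim$clusters$membership, "great_tit",
                     "adult_tarsus", seed = 2))
  expect_equal(nrow(obs), nrow(pp$obs) + sum(pp$report$rows_removed))
  expect_true(any(pp$report$rows_removed > 0))
  # at most one row per individual after deduplication
  expect_lte(max(table(pp$obs$individual_id)), 1)
  expect_equal(pp$report$rows_remaining[nrow(pp$report)], nrow(pp$obs))
})
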