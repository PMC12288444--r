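test_that("HPDI equals exhaustive window enumeration on small fixtures", {
  for (seed in 1:6) {
    set.seed(seed)
    x <- rnorm(20, sd = sample(c(0.5, 2), 1))
    expect_equal(unname(hpdi(x, 0.95)), hpdi_brute(x, 0.95))
    expect_equal(unname(hpdi(x, 0.5)), hpdi_brute(x, 0.5))
  }
  skew <- rexp(20)
  expect_equal(unname(hpdi(skew, 0.8)), hpdi_brute(skew, 0.8))
})

test_that("HPDI handles point masses and matches the normal limit", {
  expect_equal(unname(hpdi(rep(3.2, 10), 0.95)), c(3.2, 3.2))
  set.seed(99)
  z <- rnorm(1e5)
  h <- hpdi(z, 0.95)
  expect_equal(unname(h), c(-1.96, 1.96), tolerance = 0.05)
  # cross-check against the field-standard implementation (its window
  # holds round(p*n) + 1 draws where ours holds ceiling(p*n), so the
  # endpoints may differ by one order statistic)
  hc <- coda::HPDinterval(coda::mcmc(z), prob = 0.95)
  expect_equal(unname(h), c(hc[1, "lower"], hc[1, "upper"]),
               tolerance = 1e-4)
  expect_error(hpdi(numeric(0)), "empty")
})

test_that("HPDI width is non-decreasing in the probability level", {
  set.seed(8)
  x <- rt(500, df = 3)
  w <- vapply(c(0.3, 0.5, 0.8, 0.9, 0.95, 0.99),
              function(p) diff(hpdi(x, p)), numeric(1))
  expect_true(all(diff(w) >= 0))
})

test_that("HPDI midpoint tracks the median for symmetric draws", {
  set.seed(10)
  x <- rnorm(20000)
  h <- hpdi(x, 0.95)
  expect_equal(mean(h), median(x), tolerance = 0.05)
})

test_that("probability of direction counts signs with half-ties", {
  expect_equal(prob_direction(c(1, 2, 3), "positive"), 1)
  expect_equal(prob_direction(c(-1, 1, -2, 2), "positive"), 0.5)
  expect_equal(prob_direction(c(0, 0, 1, 1), "positive"), 0.75)
  set.seed(2)
  x <- c(rnorm(99), 0)
  expect_equal(prob_direction(x, "positive") +
                 prob_direction(x, "negative"), 1)
})

test_that("evidence classification follows the HPDI / pd > 0.90 rules", {
  expect_equal(evidence_class(c(0.2, 0.9), 0.99), "evidence")
  expect_equal(evidence_class(c(-0.9, -0.1), 0.99), "evidence")
  expect_equal(evidence_class(c(-0.1, 0.9), 0.91), "weak")
  expect_equal(evidence_class(c(-0.1, 0.9), 0.90), "none")
  expect_equal(evidence_class(c(-0.5, 0.5), 0.6), "none")
})

test_that("dispersion back-transformation is exact and monotone", {
  bt <- back_transform_dispersion(0.109)
  expect_equal(round_half_up(bt$pct_increase, 1), 11.5)
  expect_equal(round_half_up(
    back_transform_dispersion(0.223)$pct_increase, 0), 25)
  expect_equal(back_transform_dispersion(0)$pct_increase, 0)

  g <- seq(-0.5, 0.5, by = 0.05)
  pct <- back_transform_dispersion(g)$pct_increase
  expect_true(all(diff(pct) > 0))

  # residual SDs in original units: exp(baseline) * trait SD
  bt2 <- back_transform_dispersion(0.04, baseline_log_sd = -0.545,
                                   trait_sd = 1.035)
  expect_equal(bt2$sd_forest, exp(-0.545) * 1.035)
  expect_equal(bt2$sd_urban, exp(-0.545 + 0.04) * 1.035)
  expect_gt(bt2$sd_urban, bt2$sd_forest)
})

test_that("habitat variance contrasts work per draw", {
  n <- 400
  set.seed(3)
  draws <- cbind(sd_clust_m_forest = abs(rnorm(n, 0.25, 0.03)),
                 sd_clust_m_urban = abs(rnorm(n, 0.5, 0.05)),
                 sd_clust_d_forest = rep(0.2, n),
                 sd_clust_d_urban = rep(0.2, n))
  fit <- fake_fit(draws)
  c1 <- habitat_variance_contrast(fit, "cluster_mean")
  expect_equal(c1$diff, c1$var_urban - c1$var_forest)
  expect_equal(c1$pd, mean(c1$diff > 0))
  expect_equal(c1$estimate_urban, mean(draws[, 2]^2))

  # identical draws in both habitats: difference identically zero, pd 1/2
  c3 <- habitat_variance_contrast(fit, "cluster_dispersion")
  expect_equal(unique(c3$diff), 0)
  expect_equal(c3$pd, 0.5)
  expect_equal(c3$evidence, "none")
})

test_that("reported point estimates give the published variance ratio", {
  # among-cluster variances for great tit adult tarsus: urban 0.234,
  # forest 0.056 -> roughly four times higher in urban habitat
  n <- 100
  draws <- cbind(sd_clust_m_forest = rep(sqrt(0.056), n),
                 sd_clust_m_urban = rep(sqrt(0.234), n),
                 sd_clust_d_forest = rep(sqrt(0.059), n),
                 sd_clust_d_urban = rep(sqrt(0.058), n))
  cc <- habitat_variance_contrast(fake_fit(draws), "cluster_mean")
  expect_equal(cc$estimate_ratio, 0.234 / 0.056, tolerance = 1e-12)
  expect_equal(round(cc$estimate_ratio), 4)
})

test_that("summary rows carry every term once with coherent intervals", {
  d_fit <- dhglm(
    {
      set.seed(77)
      nC <- 6
      dhglm_data(y = rnorm(60), year_idx = rep(1:2, 30),
                 clust_idx = rep_len(1:nC, 60),
                 csys_idx = rep(1:2, each = 3),
                 chab = rep(c(0L, 1L), 3),
                 Xo_m = matrix(numeric(0), 60, 0),
                 Xo_d = matrix(numeric(0), 60, 0),
                 Xc_m = cbind(beta_0 = rep(1, nC),
                              beta_hab = rep(c(0, 1), 3)),
                 Xc_d = cbind(gamma_0 = rep(1, nC),
                              gamma_hab = rep(c(0, 1), 3)),
                 hetero = TRUE)
    }, quick_control(seed = 12))
  s <- summary(d_fit)
  tab <- s$table
  expect_equal(anyDuplicated(tab$term), 0)
  expect_setequal(
    tab$term,
    c("beta_0", "beta_hab", "gamma_0", "gamma_hab", "sd_year", "sd_sys_m",
      "sd_sys_d", "r_sys", "sd_clust_m_forest", "sd_clust_m_urban",
      "sd_clust_d_forest", "sd_clust_d_urban", "r_forest", "r_urban"))
  expect_true(all(tab$hpdi95_lo <= tab$hpdi50_lo + 1e-12))
  expect_true(all(tab$hpdi50_hi <= tab$hpdi95_hi + 1e-12))
  expect_true(all(tab$pd >= 0.5 & tab$pd <= 1))
  # random-effect rows use the 0.001 lower-bound flag and carry variances
  sd_rows <- tab[startsWith(tab$term, "sd_"), ]
  expect_equal(sd_rows$flag, sd_rows$hpdi95_lo > 0.001)
  expect_equal(sd_rows$var_estimate >= 0, rep(TRUE, nrow(sd_rows)))
  # mean/dispersion split
  expect_setequal(tab$part[tab$term %in% c("beta_0", "sd_clust_m_urban")],
                  "mean")
  expect_setequal(tab$part[tab$term %in% c("gamma_hab", "r_urban")],
                  "dispersion")
})

test_that("summary fixture values match hand-computed statistics", {
  x <- c(-2, -1, -0.5, 0.2, 0.3, 0.4, 0.5, 1, 1.5, 3)
  draws <- cbind(beta_hab = x, gamma_hab = rev(x),
                 sd_clust_m_forest = abs(x), sd_clust_m_urban = abs(x),
                 sd_clust_d_forest = abs(x), sd_clust_d_urban = abs(x))
  s <- summary(fake_fit(draws))
  row <- s$table[s$table$term == "beta_hab", ]
  expect_equal(row$estimate, mean(x))
  expect_equal(row$median, median(x))
  expect_equal(row$pd, mean(x > 0))
  expect_equal(c(row$hpdi95_lo, row$hpdi95_hi), hpdi_brute(x, 0.95))
})
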