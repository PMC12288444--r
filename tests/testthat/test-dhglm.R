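test_that("the data term of a standard-normal point is -log(2*pi)/2", {
  d <- tiny_design(1)
  d$y <- 0
  d$Xo_m[] <- 0
  params <- tiny_params()
  params$beta[] <- 0; params$gamma[] <- 0
  latent <- list(a_year = rep(0, d$nY), u_sys = matrix(0, d$nS, 2),
                 u_clust = matrix(0, d$nC, 2))
  ld <- dhglm_log_density(d, params, latent, components = TRUE)
  expect_equal(ld$data, -0.5 * log(2 * pi), tolerance = 1e-12)
})

test_that("log density equals the brute-force per-term oracle", {
  for (seed in c(13, 14, 15)) {
    d <- tiny_design(20, seed)
    params <- tiny_params(seed)
    latent <- tiny_latent(d, seed)
    expect_equal(dhglm_log_density(d, params, latent),
                 oracle_log_density(d, params, latent),
                 tolerance = 1e-8)
  }
})

test_that("the data term decreases as points move from their means", {
  d <- tiny_design(10)
  params <- tiny_params(); latent <- tiny_latent(d)
  base <- dhglm_log_density(d, params, latent, components = TRUE)$data
  prev <- base
  for (shift in c(0.5, 1, 2)) {
    d2 <- d
    d2$y <- d$y + shift * 10  # move all points far out in one direction
    cur <- dhglm_log_density(d2, params, latent, components = TRUE)$data
    expect_lt(cur, prev)
    prev <- cur
  }
})

test_that("non-finite configurations raise a diagnostic error", {
  d <- tiny_design(5)
  params <- tiny_params(); latent <- tiny_latent(d)
  bad <- params; bad$sd_year <- -0.1
  expect_error(suppressWarnings(dhglm_log_density(d, bad, latent)),
               "non-finite")
})

test_that("retained draw count honours chains x (iter - warmup) / thin", {
  d <- tiny_design(30)
  fit <- dhglm(d, dhglm_control(chains = 2, iter = 900, warmup = 300,
                                thin = 3, adapt = 150, seed = 8))
  expect_equal(coda::nchain(fit$draws), 2)
  expect_equal(coda::niter(fit$draws) * coda::nchain(fit$draws),
               2 * (900 - 300) / 3)
})

test_that("identical seeds reproduce draws exactly; new seeds differ", {
  d <- tiny_design(30)
  f1 <- dhglm(d, quick_control(seed = 4))
  f2 <- dhglm(d, quick_control(seed = 4))
  f3 <- dhglm(d, quick_control(seed = 5))
  expect_identical(as.matrix(f1$draws), as.matrix(f2$draws))
  expect_false(isTRUE(all.equal(as.matrix(f1$draws),
                                as.matrix(f3$draws))))
})

test_that("convergence diagnostics behave on known chains", {
  set.seed(21)
  iid <- coda::as.mcmc.list(lapply(1:4, function(i)
    coda::mcmc(matrix(rnorm(1000), ncol = 1,
                      dimnames = list(NULL, "theta")))))
  cc <- check_convergence(iid)
  expect_lt(max(cc$table$rhat), 1.01)
  expect_gt(min(cc$table$ess), 2000)
  expect_true(cc$pass)

  stuck <- coda::as.mcmc.list(list(
    coda::mcmc(matrix(rep(0, 500), ncol = 1,
                      dimnames = list(NULL, "theta"))),
    coda::mcmc(matrix(rep(3, 500), ncol = 1,
                      dimnames = list(NULL, "theta")))))
  cc2 <- check_convergence(stuck)
  expect_gt(max(cc2$table$rhat), 1.01)
  expect_false(cc2$pass)

  expect_error(check_convergence(iid[1]), "single chain")
})

test_that("a prior-only run reproduces the stated priors", {
  dp <- dhglm_data(y = numeric(0), year_idx = integer(0),
                   clust_idx = integer(0),
                   csys_idx = c(1L, 1L, 2L, 2L), chab = c(0L, 1L, 0L, 1L),
                   Xo_m = matrix(numeric(0), 0, 0),
                   Xo_d = matrix(numeric(0), 0, 0),
                   Xc_m = cbind(beta_0 = rep(1, 4), beta_hab = c(0, 1, 0, 1)),
                   Xc_d = cbind(gamma_0 = rep(1, 4), gamma_hab = c(0, 1, 0, 1)),
                   hetero = TRUE)
  fit <- dhglm(dp, dhglm_control(chains = 2, iter = 6000, warmup = 1000,
                                 thin = 1, adapt = 500, seed = 2))
  m <- dhglm_draws(fit, c("beta_0", "beta_hab", "gamma_hab"))
  mce <- 1 / sqrt(nrow(m) / 5)  # generous Monte-Carlo error allowance
  expect_lt(max(abs(colMeans(m))), 3 * mce)
  expect_equal(unname(apply(m, 2, sd)), rep(1, 3), tolerance = 0.1)
  # half-normal prior on a random-effect SD: mean sqrt(2/pi)
  sd_draws <- dhglm_draws(fit, "sd_clust_m_urban")
  expect_equal(mean(sd_draws), sqrt(2 / pi), tolerance = 0.1)
})

test_that("the homoscedastic reduction agrees with an independent mixed model", {
  skip_if_not_installed("lme4")
  scn <- sim_scenario(n_systems = 3, clusters_per_habitat = 3,
                      obs_per_cluster_year = 8, years = 3)
  sim <- simulate_observations(scn, seed = 55, units = "model")
  d <- sim$design
  fit <- dhglm(d, dhglm_control(chains = 2, iter = 3000, warmup = 1000,
                                thin = 2, adapt = 500, seed = 7),
               homoscedastic = TRUE)
  co <- coef(fit)
  df <- data.frame(y = d$y,
                   hab = d$Xc_m[d$clust_idx, "beta_hab"],
                   lat = d$Xc_m[d$clust_idx, "beta_lat"],
                   sex = d$Xo_m[, "beta_sex"],
                   year = factor(d$year_idx),
                   sys = factor(d$csys_idx[d$clust_idx]),
                   clust = factor(d$clust_idx))
  lm1 <- lme4::lmer(y ~ hab + lat + sex + (1 | year) + (1 | sys) +
                      (1 | clust), df, REML = FALSE)
  fe <- lme4::fixef(lm1)
  se <- sqrt(diag(as.matrix(vcov(lm1))))
  nm <- c(beta_0 = "(Intercept)", beta_hab = "hab", beta_lat = "lat",
          beta_sex = "sex")
  for (p in names(nm)) {
    expect_lt(abs(co[[p]] - fe[[nm[[p]]]]),
              max(0.1, 3 * se[[nm[[p]]]]))
  }
  expect_equal(exp(co[["gamma_0"]]), stats::sigma(lm1), tolerance = 0.05)
})

test_that("fitted values and residuals reconstruct the response", {
  d <- tiny_design(40)
  fit <- dhglm(d, quick_control(seed = 2))
  mu <- fitted(fit)
  expect_length(mu, d$n)
  expect_equal(residuals(fit), d$y - mu)
  rs <- residuals(fit, type = "scaled")
  expect_length(rs, d$n)
  expect_true(all(is.finite(rs)))
  # posterior-mean fit should track the data direction
  expect_gt(cor(mu, d$y), 0)
})

test_that("HPDI coverage is calibrated across simulation replicates", {
  # 20 desk-scale replicates x 3 parameters = 60 coverage checks of the
  # 95% HPDI; the hit count must be compatible with a 0.95 rate
  cov <- vapply(1:20, function(r) recovery_replicate(r)$covered,
                logical(3))
  hits <- sum(cov)
  expect_gte(stats::binom.test(hits, 60, 0.95)$p.value, 0.01)
})
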