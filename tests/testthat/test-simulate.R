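test_that("default parameters carry the fitted estimates per combination", {
  gt_ld <- default_params("great_tit", "lay_date")
  expect_equal(unname(gt_ld$beta["beta_hab"]), -0.256)
  bt_nt <- default_params("blue_tit", "nestling_tarsus")
  expect_equal(unname(bt_nt$gamma["gamma_hab"]), 0.223)
  gt_at <- default_params("great_tit", "adult_tarsus")
  expect_equal(unname(gt_at$re_var["clust_m_urban"]), 0.234)
  expect_equal(gt_at$re_sd, sqrt(gt_at$re_var))
  expect_equal(unname(gt_at$cor["sys"]), -0.135)
  expect_error(default_params("great_tit", "wing_length"), "unknown")
  expect_error(default_params("sparrow", "lay_date"), "unknown")
})

test_that("hypothesis switches reshape the generating parameters", {
  off <- sim_scenario(h1 = FALSE, h2 = FALSE, h3 = FALSE)
  expect_equal(off$params$re_sd[["clust_m_urban"]],
               off$params$re_sd[["clust_m_forest"]])
  expect_equal(off$params$gamma[["gamma_hab"]], 0)
  expect_equal(off$params$re_sd[["clust_d_urban"]],
               off$params$re_sd[["clust_d_forest"]])
  on <- sim_scenario()
  expect_gt(on$params$re_sd[["clust_m_urban"]],
            on$params$re_sd[["clust_m_forest"]])
  expect_error(sim_scenario(boxes_per_cluster = 4), "boxes_per_cluster")
})

test_that("the clustering rule recovers the intended landscape exactly", {
  scn <- sim_scenario(n_systems = 2, clusters_per_habitat = 3)
  land <- simulate_landscape(scn, seed = 17)
  cs <- build_clusters(land$boxes)
  expect_equal(nrow(cs$clusters), 2 * 2 * 3)
  expect_length(cs$unassigned, 0)
  got <- cs$membership$cluster_id[match(land$truth_membership$box_id,
                                        cs$membership$box_id)]
  expect_true(same_partition(got, land$truth_membership$cluster))
  # habitats survive the round trip through majority assignment
  hab_by_cluster <- tapply(land$boxes$habitat[
    match(cs$membership$box_id, land$boxes$box_id)],
    cs$membership$cluster_id, function(h) unique(h))
  expect_equal(as.character(hab_by_cluster[cs$clusters$cluster_id]),
               cs$clusters$habitat)
})

test_that("urban boxes sit on impervious cells, forest boxes do not", {
  scn <- sim_scenario(n_systems = 2, clusters_per_habitat = 2)
  land <- simulate_landscape(scn, seed = 23)
  isa_at_box <- mapply(function(lo, la)
    isa_proportion(land$isa, lo, la, 60),
    land$boxes$lon, land$boxes$lat)
  expect_true(all(isa_at_box[land$boxes$habitat == "urban"] > 0.4))
  expect_true(all(isa_at_box[land$boxes$habitat == "forest"] < 0.05))
})

test_that("observation counts and determinism are exact", {
  scn <- sim_scenario(n_systems = 2, clusters_per_habitat = 2,
                      obs_per_cluster_year = 7, years = 3)
  sim1 <- simulate_observations(scn, seed = 41)
  expect_equal(nrow(sim1$obs), 2 * 4 * 7 * 3)
  expect_equal(length(unique(sim1$obs$cluster_id)), 8)
  expect_equal(length(unique(sim1$obs$year)), 3)

  sim2 <- simulate_observations(scn, seed = 41)
  expect_equal(sim1$obs, sim2$obs)
  expect_equal(sim1$truth$latent, sim2$truth$latent)
  sim3 <- simulate_observations(scn, seed = 42)
  expect_false(isTRUE(all.equal(sim1$obs$value, sim3$obs$value)))
})

test_that("model and original units differ by the linear trait map", {
  scn <- sim_scenario(n_systems = 2, clusters_per_habitat = 2,
                      obs_per_cluster_year = 4, years = 2)
  simM <- simulate_observations(scn, seed = 44, units = "model")
  simO <- simulate_observations(scn, seed = 44, units = "original")
  ts <- simO$truth$trait_scale
  expect_equal(simO$obs$value,
               simM$obs$value * ts[["scale"]] + ts[["center"]],
               tolerance = 1e-12)
  # original-units adult tarsus values sit inside the plausible window
  expect_true(all(simO$obs$value > 12.7 & simO$obs$value < 25.5))
})

test_that("a degenerate scenario collapses onto its fixed-effect mean", {
  p <- default_params("great_tit", "adult_tarsus")
  p$re_sd[] <- 0
  p$gamma[] <- 0
  p$gamma["gamma_0"] <- -10  # residual SD exp(-10): essentially zero
  scn <- sim_scenario(n_systems = 2, clusters_per_habitat = 2,
                      obs_per_cluster_year = 4, years = 2, params = p)
  sim <- simulate_observations(scn, seed = 3, units = "model")
  d <- sim$design
  fe_mu <- drop(d$Xc_m %*% sim$truth$params$beta[colnames(d$Xc_m)]
                )[d$clust_idx] +
    drop(d$Xo_m %*% sim$truth$params$beta[colnames(d$Xo_m)])
  expect_equal(sim$obs$value, fe_mu, tolerance = 1e-3)
})

test_that("the dispersion link propagates to sample residual SD ratios", {
  # all group effects off, pure habitat effect on log residual SD;
  # at n = 10^4 per habitat the sample SD ratio converges to exp(g)
  g <- 0.223
  p <- default_params("blue_tit", "nestling_tarsus")
  p$re_sd[] <- 0
  p$beta[] <- 0
  p$gamma[] <- 0
  p$gamma["gamma_hab"] <- g
  scn <- sim_scenario(species = "blue_tit", trait = "nestling_tarsus",
                      n_systems = 2, clusters_per_habitat = 5,
                      boxes_per_cluster = 5, obs_per_cluster_year = 200,
                      years = 5, params = p)
  sim <- simulate_observations(scn, seed = 61, units = "model")
  hab <- sim$design$chab[sim$design$clust_idx]
  n_u <- sum(hab == 1); n_f <- sum(hab == 0)
  expect_gte(min(n_u, n_f), 1e4)
  ratio <- sd(sim$design$y[hab == 1]) / sd(sim$design$y[hab == 0])
  mc_se <- sqrt(1 / (2 * n_u) + 1 / (2 * n_f))  # SE of the log ratio
  expect_lt(abs(log(ratio) - g), 3 * mc_se)
})
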