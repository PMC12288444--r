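# shared fixtures and independent oracles

# place points by metre offsets in a local plane at latitude ~48 deg
boxes_at <- function(x_m, y_m, habitat = "forest", system_id = "S1",
                     ids = NULL, lat0 = 48) {
  R <- 6371008.8
  k <- pi / 180 * R
  if (is.null(ids)) ids <- sprintf("b%03d", seq_along(x_m))
  data.frame(box_id = ids, system_id = system_id,
             lon = x_m / (k * cos(lat0 * pi / 180)),
             lat = lat0 + y_m / k,
             habitat = rep(habitat, length.out = length(x_m)),
             stringsAsFactors = FALSE)
}

# transitive closure of the <= maxd adjacency graph by boolean matrix
# powering -- the brute-force clustering oracle
brute_components <- function(lon, lat, maxd) {
  n <- length(lon)
  d <- geosphere::distm(cbind(lon, lat), fun = geosphere::distGeo)
  adj <- (d <= maxd)
  reach <- adj
  repeat {
    nxt <- (reach %*% reach) > 0
    if (all(nxt == reach)) break
    reach <- nxt
  }
  comp <- integer(n)
  k <- 0
  for (i in seq_len(n)) {
    if (comp[i] == 0) {
      k <- k + 1
      comp[which(reach[i, ])] <- k
    }
  }
  comp
}

# partition comparison independent of labelling
same_partition <- function(a, b) {
  ga <- vapply(split(seq_along(a), a),
               function(g) paste(sort(g), collapse = ","), character(1))
  gb <- vapply(split(seq_along(b), b),
               function(g) paste(sort(g), collapse = ","), character(1))
  setequal(ga, gb)
}

# exhaustive shortest-window HPDI oracle
hpdi_brute <- function(x, prob) {
  s <- sort(x)
  n <- length(s)
  m <- ceiling(prob * n)
  if (m >= n) return(c(s[1], s[n]))
  best <- c(Inf, NA, NA)
  for (i in seq_len(n - m + 1)) {
    w <- s[i + m - 1] - s[i]
    if (w < best[1]) best <- c(w, s[i], s[i + m - 1])
  }
  best[2:3]
}

# quick MCMC settings for structural tests (not inference quality)
quick_control <- function(seed = 1, chains = 2)
  dhglm_control(chains = chains, iter = 800, warmup = 400, thin = 1,
                adapt = 200, seed = seed)

# small synthetic observation table (adult tarsus) for io tests
synth_obs <- function(n = 50, seed = 42) {
  set.seed(seed)
  data.frame(
    individual_id = sprintf("i%03d", seq_len(n)),
    species = sample(c("great_tit", "blue_tit"), n, TRUE),
    trait = "adult_tarsus",
    value = round(runif(n, 14, 22), 2),
    year = sample(2010:2015, n, TRUE),
    box_id = sprintf("b%02d", sample(10, n, TRUE)),
    brood_id = NA_character_,
    sex = sample(c("female", "male"), n, TRUE),
    female_age = NA_character_,
    chick_age = NA_real_,
    method = "svensson_alternative",
    stringsAsFactors = FALSE)
}

# memoised desk-scale recovery replicates shared across test files:
# replicate r simulates the default scenario with data seed 100 + r and
# fits at the reduced protocol (2 chains x 2000 iterations)
.recovery_cache <- new.env(parent = emptyenv())
recovery_replicate <- function(r) {
  key <- as.character(r)
  if (!is.null(.recovery_cache[[key]])) return(.recovery_cache[[key]])
  scn <- sim_scenario()
  sim <- simulate_observations(scn, seed = 100 + r, units = "model")
  fit <- dhglm(sim$design,
               dhglm_control(chains = 2, iter = 2000, warmup = 1000,
                             thin = 1, adapt = 500, seed = 100 + r))
  p <- sim$truth$params
  truth <- c(beta_hab = unname(p$beta[["beta_hab"]]),
             gamma_hab = unname(p$gamma[["gamma_hab"]]),
             sd_clust_m_urban = unname(p$re_sd[["clust_m_urban"]]))
  m <- dhglm_draws(fit, names(truth))
  covered <- vapply(names(truth), function(nm) {
    h <- hpdi(m[, nm], 0.95)
    h[[1]] <= truth[[nm]] && truth[[nm]] <= h[[2]]
  }, logical(1))
  res <- list(covered = covered, truth = truth,
              gamma_hab_draws = m[, "gamma_hab"])
  .recovery_cache[[key]] <- res
  res
}

# a deterministic fake fit object for summary-level tests
fake_fit <- function(draws_named, chains = 2) {
  n <- nrow(draws_named)
  half <- n / 2
  mk <- function(i) coda::mcmc(draws_named[i, , drop = FALSE])
  obj <- list(draws = coda::as.mcmc.list(list(mk(seq_len(half)),
                                              mk(half + seq_len(half)))),
              params = colnames(draws_named),
              latent_names = character(0),
              design = list(hetero = TRUE, meta = list(), scale = list(),
                            n = 0L),
              control = dhglm_control(), homoscedastic = FALSE,
              runtime = 0, diagnostics = NULL)
  class(obj) <- "dhglm"
  obj
}
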