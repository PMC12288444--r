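# Fitted DHGLM estimates for the six species x trait analyses, used as the
# generator's default parameter values. Random-effect entries are
# among-group variances (the scale on which the urban/forest ratios are
# reported); the generator simulates with their square roots as SDs.
# Columns: great/blue tit adult tarsus, great/blue tit nestling tarsus,
# great/blue tit lay date.
.uv_table1 <- local({
  cols <- c("great_tit.adult_tarsus", "blue_tit.adult_tarsus",
            "great_tit.nestling_tarsus", "blue_tit.nestling_tarsus",
            "great_tit.lay_date", "blue_tit.lay_date")
  m <- rbind(
    beta_0       = c(0.208, 0.230, -1.021, -0.716, 0.256, 0.293),
    beta_hab     = c(-0.297, -0.182, -0.409, -0.164, -0.256, -0.113),
    beta_lat     = c(0.621, 0.518, 0.518, 0.596, 0.678, 0.726),
    beta_obs     = c(0.541, 0.588, 0.085, 0.050, NA, NA),
    var_year     = c(0.038, 0.244, 0.112, 0.133, 0.395, 0.506),
    var_sys_m    = c(0.890, 1.159, 0.755, 1.044, 0.387, 0.608),
    var_cl_m_f   = c(0.056, 0.039, 0.133, 0.335, 0.162, 0.327),
    var_cl_m_u   = c(0.234, 0.144, 0.286, 0.149, 0.118, 0.063),
    gamma_0      = c(-0.545, -0.576, -0.434, -0.492, -0.734, -0.506),
    gamma_hab    = c(0.040, 0.109, 0.109, 0.223, 0.086, 0.093),
    gamma_het    = c(-0.009, 0.001, -0.001, -0.017, 0.008, -0.008),
    gamma_lat    = c(0.046, 0.290, 0.098, 0.085, -0.039, -0.036),
    gamma_area   = c(0.028, 0.161, 0.010, 0.177, -0.035, -0.024),
    gamma_years  = c(0.002, -0.001, -0.003, -0.118, 0.031, 0.089),
    gamma_obs    = c(0.020, 0.003, NA, NA, -0.030, -0.035),
    var_sys_d    = c(0.249, 0.334, 0.270, 0.082, 0.134, 0.203),
    r_sys        = c(-0.135, -0.157, -0.150, -0.046, 0.376, 0.301),
    var_cl_d_f   = c(0.059, 0.043, 0.121, 0.205, 0.151, 0.067),
    r_forest     = c(-0.291, -0.122, -0.491, -0.452, -0.144, 0.214),
    var_cl_d_u   = c(0.058, 0.109, 0.172, 0.142, 0.100, 0.161),
    r_urban      = c(-0.305, -0.013, -0.767, -0.259, -0.027, 0.068),
    n_obs        = c(13554, 8414, 7505, 2816, 6378, 4419))
  colnames(m) <- cols
  m
})

# trait location/scale in original units (mm, Julian days); the scale is
# set so that exp(gamma_0) * scale reproduces the reported forest residual
# SDs (0.60/0.49 mm adult, 0.83/0.65 mm nestling, 5.6/6.1 days lay date)
.uv_trait_scale <- list(
  "great_tit.adult_tarsus" = c(center = 19.6, scale = 1.035),
  "blue_tit.adult_tarsus" = c(center = 16.5, scale = 0.872),
  "great_tit.nestling_tarsus" = c(center = 19.2, scale = 1.281),
  "blue_tit.nestling_tarsus" = c(center = 16.3, scale = 1.063),
  "great_tit.lay_date" = c(center = 117, scale = 11.67),
  "blue_tit.lay_date" = c(center = 114, scale = 10.12))

#' Default DHGLM parameter values for a species x trait analysis
#'
#' Returns the full generating parameter set for one of the six studied
#' species x trait combinations, taken from the fitted mega-analysis
#' estimates: mean- and dispersion-part fixed effects, among-group
#' variances (year, system, forest and urban clusters, in both parts) and
#' mean-dispersion correlations. Random-effect entries are variances; the
#' element `re_sd` carries their square roots, which is what the generative
#' model uses as SDs.
#'
#' @param species `"great_tit"` or `"blue_tit"`.
#' @param trait `"adult_tarsus"`, `"nestling_tarsus"` or `"lay_date"`.
#' @return object of class `dhglm_params`: list with `beta`, `gamma`
#'   (named fixed-effect vectors), `re_var`, `re_sd`, `cor`, `trait_scale`
#'   (original-units centring) and `n_obs` (size of the source dataset).
#' @export
default_params <- function(species, trait) {
  key <- paste(species, trait, sep = ".")
  if (!key %in% colnames(.uv_table1))
    stop("unknown species x trait combination: ", species, " x ", trait)
  v <- .uv_table1[, key]
  obs_m <- switch(trait, adult_tarsus = "beta_sex",
                  nestling_tarsus = "beta_age", lay_date = NULL)
  obs_d <- switch(trait, adult_tarsus = "gamma_sex",
                  nestling_tarsus = NULL, lay_date = "gamma_fem_age")
  beta <- c(beta_0 = v[["beta_0"]], beta_hab = v[["beta_hab"]],
            beta_lat = v[["beta_lat"]])
  if (!is.null(obs_m)) beta[obs_m] <- v[["beta_obs"]]
  gamma <- c(gamma_0 = v[["gamma_0"]], gamma_hab = v[["gamma_hab"]],
             gamma_het = v[["gamma_het"]], gamma_lat = v[["gamma_lat"]],
             gamma_area = v[["gamma_area"]],
             gamma_years = v[["gamma_years"]])
  if (!is.null(obs_d)) gamma[obs_d] <- v[["gamma_obs"]]
  re_var <- c(year = v[["var_year"]], sys_m = v[["var_sys_m"]],
              clust_m_forest = v[["var_cl_m_f"]],
              clust_m_urban = v[["var_cl_m_u"]],
              sys_d = v[["var_sys_d"]],
              clust_d_forest = v[["var_cl_d_f"]],
              clust_d_urban = v[["var_cl_d_u"]])
  structure(list(species = species, trait = trait,
                 beta = beta, gamma = gamma,
                 re_var = re_var, re_sd = sqrt(re_var),
                 cor = c(sys = v[["r_sys"]], forest = v[["r_forest"]],
                         urban = v[["r_urban"]]),
                 trait_scale = .uv_trait_scale[[key]],
                 n_obs = v[["n_obs"]]),
            class = "dhglm_params")
}

#' @export
print.dhglm_params <- function(x, ...) {
  cat(sprintf("DHGLM parameters (%s %s):\n", x$species, x$trait))
  cat("  mean part: ", paste(names(x$beta), round(x$beta, 3), sep = "=",
                             collapse = ", "), "\n")
  cat("  dispersion:", paste(names(x$gamma), round(x$gamma, 3), sep = "=",
                             collapse = ", "), "\n")
  cat("  RE variances:", paste(names(x$re_var), round(x$re_var, 3),
                               sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Define a synthetic gradient-study scenario
#'
#' Desk-scale defaults: 4 study systems, each with 5 urban and 5 forest
#' clusters of 10 nest boxes, 10 individuals per cluster-year over 5 years
#' (about 2000 observations) — large enough for parameter recovery yet
#' fast to fit. Generating parameters default to the fitted estimates for
#' the chosen species and trait ([default_params()]); the hypothesis
#' switches modify them: with `h1 = FALSE` the urban among-cluster SD in
#' the mean part is set equal to the forest one, with `h2 = FALSE` the
#' dispersion urbanisation coefficient is zeroed, and with `h3 = FALSE`
#' the urban among-cluster SD in the dispersion part equals the forest
#' one.
#'
#' @param species,trait canonical tokens.
#' @param n_systems number of study systems.
#' @param clusters_per_habitat clusters per habitat per system.
#' @param boxes_per_cluster nest boxes per cluster (>= 5).
#' @param obs_per_cluster_year individuals sampled per cluster and year.
#' @param years number of breeding seasons.
#' @param params generating [default_params()]-style object (optional).
#' @param h1,h2,h3 hypothesis switches (see Details).
#' @return object of class `sim_scenario`.
#' @export
sim_scenario <- function(species = "great_tit", trait = "adult_tarsus",
                         n_systems = 4, clusters_per_habitat = 5,
                         boxes_per_cluster = 10, obs_per_cluster_year = 10,
                         years = 5, params = NULL,
                         h1 = TRUE, h2 = TRUE, h3 = TRUE) {
  stopifnot(n_systems >= 1, clusters_per_habitat >= 1,
            boxes_per_cluster >= 5, obs_per_cluster_year >= 1, years >= 1)
  if (is.null(params)) params <- default_params(species, trait)
  if (!isTRUE(h1))
    params$re_sd["clust_m_urban"] <- params$re_sd["clust_m_forest"]
  if (!isTRUE(h2)) params$gamma["gamma_hab"] <- 0
  if (!isTRUE(h3))
    params$re_sd["clust_d_urban"] <- params$re_sd["clust_d_forest"]
  params$re_var <- params$re_sd^2
  structure(list(species = species, trait = trait,
                 n_systems = n_systems,
                 clusters_per_habitat = clusters_per_habitat,
                 boxes_per_cluster = boxes_per_cluster,
                 obs_per_cluster_year = obs_per_cluster_year,
                 years = years, params = params,
                 h1 = isTRUE(h1), h2 = isTRUE(h2), h3 = isTRUE(h3)),
            class = "sim_scenario")
}

#' Simulate the landscape of a gradient study
#'
#' Places nest boxes so that the intended clusters are recoverable by the
#' clustering rule — boxes within a cluster form a 120 m grid (chained
#' well inside the 300 m linkage), distinct clusters are >= 700 m apart —
#' and builds matching toy rasters: impervious surface ~0.46 on urban
#' cluster disks against a ~0.01 background, and a mosaic of land-cover
#' classes inside urban disks against a uniform forest class.
#'
#' @param scenario a [sim_scenario()].
#' @param seed integer seed (placement jitter).
#' @return list with `boxes` (nest-box data frame), `isa` and `landcover`
#'   ([toy_raster()]s) and `truth_membership` (intended box -> cluster
#'   partition).
#' @export
simulate_landscape <- function(scenario, seed = 1L) {
  sc <- scenario
  lat0 <- 48; R <- 6371008.8; k <- pi / 180 * R
  n_cl <- 2 * sc$clusters_per_habitat
  cols_per_cl <- ceiling(sc$boxes_per_cluster / 2)
  width <- (cols_per_cl - 1) * 120
  spacing <- width + 800

  # habitats alternate along the transect and north/south rows alternate
  # independently of habitat, so latitude is not confounded with habitat
  boxes <- uv_with_seed(seed, {
    acc <- list()
    for (s in seq_len(sc$n_systems)) {
      sys_id <- sprintf("S%d", s)
      x_sys <- (s - 1) * (n_cl * spacing + 5000)
      for (j in seq_len(n_cl)) {
        hab <- .uv_habitats[2 - j %% 2]  # odd slots urban, even forest
        ci <- ceiling(j / 2)
        y_c <- (if (((j - 1) %/% 2) %% 2 == 0) 2000 else -2000) +
          runif(1, -300, 300)
        x_c <- x_sys + (j - 1) * spacing
        idx <- seq_len(sc$boxes_per_cluster)
        bx <- x_c + ((idx - 1) %% cols_per_cl) * 120 +
          runif(sc$boxes_per_cluster, -20, 20)
        by <- y_c + ((idx - 1) %/% cols_per_cl) * 120 +
          runif(sc$boxes_per_cluster, -20, 20)
        cl_label <- sprintf("%s_%s%d", sys_id, substring(hab, 1, 1), ci)
        acc[[cl_label]] <- data.frame(
          box_id = sprintf("%s_b%03d", cl_label, idx),
          system_id = sys_id,
          lon = bx / (k * cos(lat0 * pi / 180)),
          lat = lat0 + by / k,
          habitat = hab, truth_cluster = cl_label,
          stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, unname(acc))
  })

  # raster frame in the same local plane, anchored 1500 m outside the boxes
  xm <- (boxes$lon) * k * cos(lat0 * pi / 180)
  ym <- (boxes$lat - lat0) * k
  x0 <- min(xm) - 1500; y0 <- min(ym) - 1500
  nx <- ceiling((max(xm) + 1500 - x0) / 50)
  ny <- ceiling((max(ym) + 1500 - y0) / 50)
  origin_lon <- x0 / (k * cos(lat0 * pi / 180))
  origin_lat <- lat0 + y0 / k

  centres <- stats::aggregate(cbind(xm, ym) ~ truth_cluster + habitat,
                              data.frame(xm = xm - x0, ym = ym - y0,
                                         truth_cluster = boxes$truth_cluster,
                                         habitat = boxes$habitat),
                              FUN = mean)
  is_u <- centres$habitat == "urban"
  ucx <- centres$xm[is_u]; ucy <- centres$ym[is_u]
  fcx <- centres$xm[!is_u]; fcy <- centres$ym[!is_u]

  cell_isa <- 50
  xc <- (seq_len(nx) - 0.5) * cell_isa
  yc <- (seq_len(ny) - 0.5) * cell_isa
  isa_vals <- matrix(0.01, ny, nx)
  lc_cell <- 100
  lnx <- ceiling(nx / 2); lny <- ceiling(ny / 2)
  lc_vals <- matrix(1L, lny, lnx)
  lxc <- (seq_len(lnx) - 0.5) * lc_cell
  lyc <- (seq_len(lny) - 0.5) * lc_cell
  for (j in seq_along(ucx)) {
    d2 <- outer((yc - ucy[j])^2, (xc - ucx[j])^2, "+")
    isa_vals[d2 <= 700^2] <- 0.46
    ld2 <- outer((lyc - ucy[j])^2, (lxc - ucx[j])^2, "+")
    in_disk <- which(ld2 <= 1200^2)
    # urban mosaics differ in richness (2-4 classes) between clusters so
    # land-cover heterogeneity varies within the urban habitat
    n_classes <- 2L + (j - 1L) %% 3L
    lc_vals[in_disk] <- 2L + (in_disk %% n_classes)
  }
  for (j in seq_along(fcx)) {
    # every other forest cluster sits in mixed forest/meadow cover
    if (j %% 2 == 0) next
    ld2 <- outer((lyc - fcy[j])^2, (lxc - fcx[j])^2, "+")
    in_disk <- which(ld2 <= 1200^2)
    lc_vals[in_disk] <- ifelse(in_disk %% 4L == 0L, 6L, 1L)
  }

  truth_membership <- data.frame(box_id = boxes$box_id,
                                 cluster = boxes$truth_cluster,
                                 stringsAsFactors = FALSE)
  boxes$truth_cluster <- NULL
  list(boxes = boxes,
       isa = toy_raster(isa_vals, origin_lon, origin_lat, cell_isa),
       landcover = toy_raster(lc_vals, origin_lon, origin_lat, lc_cell),
       truth_membership = truth_membership)
}

#' Simulate trait observations from the DHGLM generative model
#'
#' Runs the full generative process: landscape ([simulate_landscape()]),
#' clustering and environmental extraction, covariate draws (balanced sex,
#' uniform chick age 13-17, ~40% yearling females), latent group effects
#' from their bivariate normals (habitat-specific SDs and mean-dispersion
#' correlations) and finally `y ~ Normal(mu, sigma)` with
#' `log sigma` from the dispersion part. The latent truth is returned so
#' recovery tests never re-derive anything. The same seed reproduces the
#' identical table.
#'
#' @param scenario a [sim_scenario()].
#' @param seed integer seed.
#' @param units `"original"` emits trait values in mm / Julian days using
#'   the scenario's trait centring; `"model"` emits the Z-scale values the
#'   model is defined on (used for exact parameter recovery).
#' @return list with `obs` (observation table), `boxes`, `clusters` (a
#'   [build_clusters()] result with environmental metrics), `design` (the
#'   [dhglm_data()] used for generation) and `truth` (generating
#'   parameters, latent effects and the model-scale response).
#' @export
simulate_observations <- function(scenario, seed = 1L,
                                  units = c("original", "model")) {
  units <- match.arg(units)
  sc <- scenario
  land <- simulate_landscape(sc, seed)
  cl_set <- build_clusters(land$boxes)
  cl_set <- attach_env(cl_set, land$isa, land$landcover)

  cl <- cl_set$clusters
  memb <- cl_set$membership
  nC <- nrow(cl)

  obs <- uv_with_seed(seed + 1L, {
    rows <- vector("list", nC * sc$years)
    ri <- 0
    for (ci in seq_len(nC)) {
      member_boxes <- memb$box_id[memb$cluster_id == cl$cluster_id[ci]]
      for (t in seq_len(sc$years)) {
        ri <- ri + 1
        nr <- sc$obs_per_cluster_year
        id <- sprintf("%s_y%d_i%02d", cl$cluster_id[ci], t, seq_len(nr))
        rows[[ri]] <- data.frame(
          individual_id = id,
          species = sc$species, trait = sc$trait, value = 0,
          year = 2000L + t,
          box_id = member_boxes[1 + (seq_len(nr) - 1) %% length(member_boxes)],
          brood_id = if (sc$trait == "nestling_tarsus") paste0(id, "_br")
                     else NA_character_,
          sex = sample(c("female", "male"), nr, replace = TRUE),
          female_age = sample(c("yearling", "older"), nr, replace = TRUE,
                              prob = c(0.4, 0.6)),
          chick_age = sample(13:17, nr, replace = TRUE),
          method = "svensson_alternative",
          stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, rows)
  })
  obs$cluster_id <- memb$cluster_id[match(obs$box_id, memb$box_id)]

  design <- build_design(obs, cl_set, sc$species, sc$trait,
                         mode = "categorical",
                         standardize_response = FALSE)

  p <- sc$params
  truth <- uv_with_seed(seed + 2L, {
    a_year <- rnorm(design$nY, 0, p$re_sd[["year"]])
    u_sys <- uv_rbinorm(design$nS, p$re_sd[["sys_m"]], p$re_sd[["sys_d"]],
                        p$cor[["sys"]])
    hab <- design$chab  # 0 forest, 1 urban
    sm <- ifelse(hab == 1, p$re_sd[["clust_m_urban"]],
                 p$re_sd[["clust_m_forest"]])
    sd_ <- ifelse(hab == 1, p$re_sd[["clust_d_urban"]],
                  p$re_sd[["clust_d_forest"]])
    rr <- ifelse(hab == 1, p$cor[["urban"]], p$cor[["forest"]])
    u_clust <- t(vapply(seq_len(design$nC), function(cc)
      drop(uv_rbinorm(1, sm[cc], sd_[cc], rr[cc])), numeric(2)))
    list(a_year = a_year, u_sys = u_sys, u_clust = u_clust)
  })

  beta <- p$beta[c(colnames(design$Xc_m), colnames(design$Xo_m))]
  gamma <- p$gamma[c(colnames(design$Xc_d), colnames(design$Xo_d))]
  if (any(is.na(beta)) || any(is.na(gamma)))
    stop("generating parameters do not cover the design columns")
  pc_m <- ncol(design$Xc_m); pc_d <- ncol(design$Xc_d)
  mu <- drop(design$Xc_m %*% beta[seq_len(pc_m)])[design$clust_idx] +
    truth$a_year[design$year_idx] +
    truth$u_sys[design$csys_idx[design$clust_idx], 1] +
    truth$u_clust[design$clust_idx, 1]
  log_sd <- drop(design$Xc_d %*% gamma[seq_len(pc_d)])[design$clust_idx] +
    truth$u_sys[design$csys_idx[design$clust_idx], 2] +
    truth$u_clust[design$clust_idx, 2]
  if (ncol(design$Xo_m) > 0)
    mu <- mu + drop(design$Xo_m %*% beta[-seq_len(pc_m)])
  if (ncol(design$Xo_d) > 0)
    log_sd <- log_sd + drop(design$Xo_d %*% gamma[-seq_len(pc_d)])

  y <- uv_with_seed(seed + 3L, rnorm(design$n, mu, exp(log_sd)))
  design$y <- y

  ts <- p$trait_scale
  obs$value <- if (units == "original")
    y * ts[["scale"]] + ts[["center"]] else y

  list(obs = obs, boxes = land$boxes, clusters = cl_set, design = design,
       truth = list(params = p, latent = truth, y_model = y,
                    mu = mu, log_sd = log_sd,
                    units = units, trait_scale = ts,
                    truth_membership = land$truth_membership),
       scenario = sc)
}

# n draws from a zero-mean bivariate normal (rows), via the Cholesky map;
# degenerate SDs of 0 are allowed
uv_rbinorm <- function(n, s1, s2, r) {
  z1 <- rnorm(n); z2 <- rnorm(n)
  cbind(s1 * z1, s2 * (r * z1 + sqrt(1 - r^2) * z2))
}
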