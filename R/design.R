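#' Trait-specific covariate configuration
#'
#' Which observation-level covariates enter each model part: adult tarsus
#' carries sex in both the mean and dispersion parts; nestling tarsus
#' carries chick age in the mean part only (nestlings cannot be reliably
#' sexed); lay date carries female age (yearling vs. older) in the
#' dispersion part only (lay date is a female trait, so no sex term).
#'
#' @param trait canonical trait token.
#' @return list with character vectors `mean_obs` and `disp_obs`.
#' @export
trait_config <- function(trait) {
  switch(trait,
    adult_tarsus = list(mean_obs = "sex", disp_obs = "sex"),
    nestling_tarsus = list(mean_obs = "chick_age", disp_obs = character(0)),
    lay_date = list(mean_obs = character(0), disp_obs = "female_age"),
    stop("unknown trait: ", trait))
}

#' Construct a DHGLM model dataset
#'
#' Low-level validated container for [dhglm()]. Most users should call
#' [build_design()] instead.
#'
#' @param y numeric response vector (may be length 0 for prior-only runs).
#' @param year_idx,clust_idx integer observation indices into years and
#'   clusters (1-based, dense).
#' @param csys_idx integer system index per cluster.
#' @param chab 0/1 urban indicator per cluster.
#' @param Xo_m,Xo_d observation-level design matrices for the mean and
#'   dispersion parts (0-column matrices when a part has no
#'   observation-level covariate).
#' @param Xc_m,Xc_d cluster-level design matrices (including intercept).
#' @param hetero logical; fit habitat-specific among-cluster variances
#'   (categorical urbanisation mode) or a single variance per part (ISA
#'   modes).
#' @param scale list of centring information for back-transformation.
#' @param meta list of labels (species, trait, mode, level names).
#' @return an object of class `dhglm_data`.
#' @export
dhglm_data <- function(y, year_idx, clust_idx, csys_idx, chab,
                       Xo_m, Xo_d, Xc_m, Xc_d, hetero = TRUE,
                       scale = list(), meta = list()) {
  n <- length(y); nC <- length(csys_idx)
  stopifnot(length(year_idx) == n, length(clust_idx) == n,
            length(chab) == nC, is.matrix(Xc_m), is.matrix(Xc_d),
            nrow(Xc_m) == nC, nrow(Xc_d) == nC,
            is.matrix(Xo_m), is.matrix(Xo_d),
            nrow(Xo_m) == n || ncol(Xo_m) == 0,
            nrow(Xo_d) == n || ncol(Xo_d) == 0)
  if (n > 0) {
    stopifnot(all(clust_idx >= 1 & clust_idx <= nC),
              all(year_idx >= 1), all(is.finite(y)))
  }
  stopifnot(all(chab %in% c(0, 1)), all(csys_idx >= 1))
  structure(list(
    y = as.numeric(y),
    year_idx = as.integer(year_idx), clust_idx = as.integer(clust_idx),
    csys_idx = as.integer(csys_idx), chab = as.integer(chab),
    Xo_m = Xo_m, Xo_d = Xo_d, Xc_m = Xc_m, Xc_d = Xc_d,
    n = as.integer(n), nY = max(1L, suppressWarnings(max(year_idx, -Inf)),
                                na.rm = TRUE),
    nS = as.integer(max(csys_idx)), nC = as.integer(nC),
    hetero = isTRUE(hetero), scale = scale, meta = meta),
    class = "dhglm_data")
}

#' @export
print.dhglm_data <- function(x, ...) {
  cat(sprintf(paste0("DHGLM dataset: %d obs, %d clusters (%d urban), ",
                     "%d systems, %d years\n"),
              x$n, x$nC, sum(x$chab), x$nS, x$nY))
  cat("  mean part:", paste(c(colnames(x$Xc_m), colnames(x$Xo_m)),
                            collapse = ", "), "\n")
  cat("  dispersion part:", paste(c(colnames(x$Xc_d), colnames(x$Xo_d)),
                                  collapse = ", "), "\n")
  invisible(x)
}

#' Build the DHGLM design from preprocessed observations
#'
#' Assembles the model-ready dataset for one species x trait analysis.
#' The mean part contains an intercept, the urbanisation term (urban
#' habitat dummy, forest = 0, or standardised ISA), standardised cluster
#' mean latitude and the trait's observation-level covariate
#' ([trait_config()]). The dispersion part contains an intercept, the
#' urbanisation term, standardised land-cover Shannon diversity, latitude,
#' cluster area and number of years studied, plus the trait's
#' observation-level dispersion covariate. Under the categorical mode the
#' among-cluster random effects get habitat-specific variances; under the
#' ISA modes a single variance is fitted per part.
#'
#' Continuous cluster-level covariates are standardised across clusters;
#' observation-level continuous covariates across observations; the
#' response is standardised across the combined dataset (disable via
#' `standardize_response` when the response is already on the model scale).
#'
#' @param obs preprocessed observations carrying `cluster_id` (from
#'   [preprocess_trait()]).
#' @param cluster_set a [build_clusters()] result whose clusters carry
#'   environmental metrics ([attach_env()]).
#' @param species,trait canonical tokens.
#' @param mode urbanisation mode: `"categorical"`, `"isa_100"` or
#'   `"isa_1000"`.
#' @param standardize_response logical; Z-transform the response.
#' @return a [dhglm_data()] object.
#' @export
build_design <- function(obs, cluster_set, species, trait,
                         mode = c("categorical", "isa_100", "isa_1000"),
                         standardize_response = TRUE) {
  mode <- match.arg(mode)
  cfg <- trait_config(trait)
  cl <- if (inherits(cluster_set, "cluster_set")) cluster_set$clusters else
    cluster_set
  obs <- obs[obs$species == species & obs$trait == trait, , drop = FALSE]
  if (!"cluster_id" %in% names(obs))
    stop("observations must carry cluster_id; run preprocess_trait() first")
  obs <- obs[obs$cluster_id %in% cl$cluster_id, , drop = FALSE]
  if (nrow(obs) == 0) stop("no observations left for ", species, " ", trait)

  # drop rows missing a required observation-level covariate
  for (v in unique(c(cfg$mean_obs, cfg$disp_obs))) {
    bad <- is.na(obs[[v]])
    if (any(bad)) {
      uv_log("build_design: dropped %d row(s) missing %s", sum(bad), v)
      obs <- obs[!bad, , drop = FALSE]
    }
  }

  # restrict clusters to those observed; recompute years studied
  cl <- cl[cl$cluster_id %in% unique(obs$cluster_id), , drop = FALSE]
  cl <- cl[order(cl$cluster_id), , drop = FALSE]
  yrs <- tapply(obs$year, obs$cluster_id, function(y) length(unique(y)))
  cl$years_studied <- as.integer(yrs[cl$cluster_id])

  if (mode != "categorical" && !all(c("isa_100", "isa_1000") %in% names(cl)))
    stop("ISA mode requires environmental metrics; run attach_env() first")
  if (!"shannon_h" %in% names(cl))
    stop("clusters lack shannon_h; run attach_env() first")

  clust_idx <- match(obs$cluster_id, cl$cluster_id)
  sys_levels <- sort(unique(cl$system_id))
  csys_idx <- match(cl$system_id, sys_levels)
  year_levels <- sort(unique(obs$year))
  year_idx <- match(obs$year, year_levels)
  chab <- as.integer(cl$habitat == "urban")

  # constant covariates (possible in balanced designs) are centred to an
  # all-zero column: the coefficient stays in the model but is informed by
  # its prior only
  zs <- function(x, name) {
    if (length(unique(x)) == 1L) {
      uv_log("build_design: covariate '%s' is constant; centred to zero",
             name)
      return(rep(0, length(x)))
    }
    standardize(x, name)$z
  }
  urb_col <- switch(mode,
    categorical = chab,
    isa_100 = zs(cl$isa_100, "isa_100"),
    isa_1000 = zs(cl$isa_1000, "isa_1000"))
  urb_name <- switch(mode, categorical = "hab",
                     isa_100 = "isa100", isa_1000 = "isa1000")

  Xc_m <- cbind(1, urb_col, zs(cl$mean_lat, "latitude"))
  colnames(Xc_m) <- c("beta_0", paste0("beta_", urb_name), "beta_lat")
  Xc_d <- cbind(1, urb_col, zs(cl$shannon_h, "shannon_h"),
                zs(cl$mean_lat, "latitude"), zs(cl$area_km2, "area_km2"),
                zs(cl$years_studied, "years_studied"))
  colnames(Xc_d) <- c("gamma_0", paste0("gamma_", urb_name), "gamma_het",
                      "gamma_lat", "gamma_area", "gamma_years")

  obs_col <- function(v) {
    switch(v,
      sex = {
        bad <- setdiff(unique(obs$sex), c("female", "male"))
        if (length(bad)) stop("unknown sex value(s): ",
                              paste(bad, collapse = ", "))
        as.numeric(obs$sex == "male")
      },
      chick_age = zs(as.numeric(obs$chick_age), "chick_age"),
      female_age = {
        bad <- setdiff(unique(obs$female_age), c("yearling", "older"))
        if (length(bad)) stop("unknown female_age value(s): ",
                              paste(bad, collapse = ", "))
        as.numeric(obs$female_age == "yearling")
      },
      stop("covariate '", v, "' is not available for trait ", trait))
  }
  om_name <- c(sex = "beta_sex", chick_age = "beta_age")
  od_name <- c(sex = "gamma_sex", female_age = "gamma_fem_age")
  Xo_m <- matrix(numeric(0), nrow(obs), 0)
  for (v in cfg$mean_obs)
    Xo_m <- cbind(Xo_m, setNames(data.frame(obs_col(v)), om_name[[v]]))
  Xo_m <- as.matrix(Xo_m)
  Xo_d <- matrix(numeric(0), nrow(obs), 0)
  for (v in cfg$disp_obs)
    Xo_d <- cbind(Xo_d, setNames(data.frame(obs_col(v)), od_name[[v]]))
  Xo_d <- as.matrix(Xo_d)

  scale <- list(response = NULL)
  y <- obs$value
  if (standardize_response) {
    st <- standardize(y, "response")
    y <- st$z
    scale$response <- c(center = st$center, scale = st$scale)
  }

  dhglm_data(
    y = y, year_idx = year_idx, clust_idx = clust_idx,
    csys_idx = csys_idx, chab = chab,
    Xo_m = Xo_m, Xo_d = Xo_d, Xc_m = Xc_m, Xc_d = Xc_d,
    hetero = (mode == "categorical"), scale = scale,
    meta = list(species = species, trait = trait, mode = mode,
                cluster_ids = cl$cluster_id, system_ids = sys_levels,
                year_levels = year_levels,
                cluster_habitat = cl$habitat))
}
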