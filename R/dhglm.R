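#' Fit the double-hierarchical Gaussian model
#'
#' Fits a Bayesian location-scale mixed model in which the trait mean and
#' the log residual standard deviation each carry fixed effects and random
#' effects:
#' \deqn{y_i \sim N(\mu_i, \sigma_i^2)}
#' \deqn{\mu_i = x_i^\top\beta + a_{year(i)} + a_{sys(i)} + a_{clust(i)}}
#' \deqn{\log\sigma_i = z_i^\top\gamma + b_{sys(i)} + b_{clust(i)}}
#' The system pair \eqn{(a_{sys}, b_{sys})} and the cluster pair
#' \eqn{(a_{clust}, b_{clust})} are bivariate normal with a mean-dispersion
#' correlation; under the categorical urbanisation mode the cluster pair
#' gets habitat-specific standard deviations and correlations (forest vs.
#' urban blocks), which carry the among-cluster variance in means
#' ("parameter 1") and the among-cluster variance in residual variance
#' ("parameter 3"). The urban coefficient in the dispersion part is the
#' within-cluster heterogeneity effect ("parameter 2"). Year effects enter
#' the mean part only.
#'
#' Priors: Normal(0, 1) on fixed effects, half-Normal(0, 1) on random-effect
#' SDs and LKJ(df = 2) on each 2x2 correlation matrix (implemented exactly
#' as \eqn{(r+1)/2 \sim Beta(2,2)}). These are weakly informative on the
#' Z-transformed response scale.
#'
#' Sampling uses JAGS (Gibbs/slice) through \pkg{rjags} with a
#' hierarchically centred parameterisation: group effects are drawn around
#' their level-specific linear predictors, which mixes far better under
#' conditional sampling than non-centring. Identical `control` (seed,
#' chains, iterations) and data give identical draws.
#'
#' @param design a [dhglm_data()] object, usually from [build_design()].
#' @param control MCMC settings from [dhglm_control()].
#' @param homoscedastic logical; if `TRUE`, fit the reduced model with a
#'   single residual SD (dispersion part collapsed to its intercept and no
#'   dispersion random effects) — a standard Gaussian mixed model used for
#'   cross-validation against independent mixed-model software.
#' @param monitor_latent logical; also retain draws of the latent group
#'   effects (needed by [fitted.dhglm()] and [residuals.dhglm()]).
#' @param quiet suppress JAGS progress output.
#' @return an object of class `dhglm` with elements `draws` (a
#'   [coda::mcmc.list] with canonical parameter names), `params` (monitored
#'   model parameter names), `design`, `control`, `diagnostics` (split-Rhat
#'   and effective sample sizes from [check_convergence()]) and `runtime`.
#' @seealso [summary.dhglm()], [habitat_variance_contrast()],
#'   [check_convergence()]
#' @export
dhglm <- function(design, control = dhglm_control(), homoscedastic = FALSE,
                  monitor_latent = TRUE, quiet = TRUE) {
  stopifnot(inherits(design, "dhglm_data"),
            inherits(control, "dhglm_control"))
  spec <- uv_jags_spec(design, homoscedastic)
  monitors <- spec$params
  if (monitor_latent) monitors <- c(monitors, spec$latents)

  # the glm module block-samples conjugate normal sub-graphs (fixed plus
  # random effects jointly), which removes the crossed-intercept ridge
  rjags::load.module("glm", quiet = TRUE)
  # central starting values: latents at zero, SDs at 0.5, correlations at
  # 0; keeps the block samplers well-conditioned from the first iteration
  # (prior-drawn dispersion latents can produce likelihood weights that
  # overflow the normal-equation solve). Chains differ through their RNGs.
  inits <- lapply(seq_len(control$chains), function(ch)
    c(uv_jags_inits(spec),
      list(.RNG.name = "base::Mersenne-Twister",
           .RNG.seed = control$seed * 1000L + ch)))
  t0 <- Sys.time()
  # a short adaptation slice before the burn-in is intentional; JAGS's
  # note about it is not actionable here
  jm <- withCallingHandlers(
    rjags::jags.model(textConnection(spec$model), data = spec$data,
                      inits = inits, n.chains = control$chains,
                      n.adapt = control$adapt, quiet = quiet),
    warning = function(w) {
      if (grepl("Adaptation incomplete", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  burn <- control$warmup - control$adapt
  if (burn > 0) stats::update(jm, n.iter = burn,
                              progress.bar = if (quiet) "none" else "text")
  draws <- rjags::coda.samples(jm, variable.names = monitors,
                               n.iter = control$iter - control$warmup,
                               thin = control$thin,
                               progress.bar = if (quiet) "none" else "text")
  runtime <- as.numeric(difftime(Sys.time(), t0, units = "secs"))

  draws <- uv_rename_draws(draws, spec)
  fit <- structure(list(draws = draws, params = spec$param_names,
                        latent_names = if (monitor_latent) spec$latent_names
                                       else character(0),
                        design = design, control = control,
                        homoscedastic = homoscedastic,
                        runtime = runtime),
                   class = "dhglm")
  fit$diagnostics <- if (control$chains >= 2)
    check_convergence(fit) else NULL
  fit
}

#' @export
print.dhglm <- function(x, digits = 3, ...) {
  m <- x$design$meta
  cat("Double-hierarchical Gaussian model",
      if (x$homoscedastic) "(reduced: homoscedastic)", "\n")
  if (length(m))
    cat(sprintf("  %s %s, urbanisation mode '%s'\n",
                m$species, m$trait, m$mode))
  cat(sprintf("  %d obs, %d clusters, %d systems, %d years\n",
              x$design$n, x$design$nC, x$design$nS, x$design$nY))
  cat(sprintf("  %d chains x %d iter (warmup %d, thin %d): %d draws, %.1f s\n",
              x$control$chains, x$control$iter, x$control$warmup,
              x$control$thin, coda::niter(x$draws) * coda::nchain(x$draws),
              x$runtime))
  if (!is.null(x$diagnostics)) {
    d <- x$diagnostics$table
    cat(sprintf("  convergence: max split-Rhat %.3f, min ESS %.0f (%s)\n",
                max(d$rhat), min(d$ess),
                if (x$diagnostics$pass) "pass" else "CHECK"))
  }
  est <- coef(x)
  cat("  posterior means:\n")
  print(round(est, digits))
  invisible(x)
}

#' @export
coef.dhglm <- function(object, ...) {
  m <- as.matrix(object$draws)
  colMeans(m[, object$params, drop = FALSE])
}

#' Posterior draws of model parameters as a matrix
#' @param fit a fitted [dhglm()] object.
#' @param pars optional character vector of parameter names.
#' @return matrix of retained draws (rows) by parameters (columns).
#' @export
dhglm_draws <- function(fit, pars = NULL) {
  m <- as.matrix(fit$draws)
  if (is.null(pars)) pars <- fit$params
  missing <- setdiff(pars, colnames(m))
  if (length(missing))
    stop("parameter(s) not monitored: ", paste(missing, collapse = ", "))
  m[, pars, drop = FALSE]
}

#' @export
fitted.dhglm <- function(object, ...) {
  uv_linpred(object)$mu
}

#' @export
residuals.dhglm <- function(object, type = c("response", "scaled"), ...) {
  type <- match.arg(type)
  lp <- uv_linpred(object)
  r <- object$design$y - lp$mu
  if (type == "scaled") r <- r / lp$sigma
  r
}

#' Split-Rhat and effective sample size diagnostics
#'
#' Computes the split-\eqn{\hat R} statistic (each chain halved, so a
#' within-chain trend inflates \eqn{\hat R}) and the effective sample size
#' for every monitored model parameter. The pass rule follows the study
#' protocol operationalised as split-Rhat <= `rhat_max` and ESS >
#' `ess_min`.
#'
#' @param fit a fitted [dhglm()] object, or a [coda::mcmc.list].
#' @param rhat_max split-Rhat pass threshold (default 1.01).
#' @param ess_min effective-sample-size pass threshold (default 400).
#' @param pars parameters to check (defaults to the model parameters of a
#'   `dhglm` fit, or all columns of a bare `mcmc.list`).
#' @return list with `table` (data frame: parameter, rhat, ess,
#'   pass flags) and `pass` (overall logical).
#' @export
check_convergence <- function(fit, rhat_max = 1.01, ess_min = 400,
                              pars = NULL) {
  if (inherits(fit, "dhglm")) {
    draws <- fit$draws
    if (is.null(pars)) pars <- fit$params
  } else {
    draws <- fit
    if (is.null(pars)) pars <- coda::varnames(draws)
  }
  if (coda::nchain(draws) < 2)
    stop("Rhat is undefined for a single chain; run at least 2 chains")
  mats <- lapply(draws, function(ch) as.matrix(ch)[, pars, drop = FALSE])
  rhat <- vapply(pars, function(p)
    uv_split_rhat(lapply(mats, function(m) m[, p])), numeric(1))
  ess <- vapply(pars, function(p) {
    x <- coda::as.mcmc.list(lapply(mats, function(m) coda::mcmc(m[, p])))
    as.numeric(coda::effectiveSize(x))
  }, numeric(1))
  tab <- data.frame(parameter = pars, rhat = rhat, ess = ess,
                    rhat_ok = rhat <= rhat_max, ess_ok = ess > ess_min,
                    stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  list(table = tab, pass = all(tab$rhat_ok & tab$ess_ok),
       rhat_max = rhat_max, ess_min = ess_min)
}

# split-Rhat over a list of per-chain vectors
uv_split_rhat <- function(chains) {
  halves <- unlist(lapply(chains, function(x) {
    h <- floor(length(x) / 2)
    list(x[seq_len(h)], x[seq.int(h + 1, 2 * h)])
  }), recursive = FALSE)
  m <- length(halves); n <- length(halves[[1]])
  means <- vapply(halves, mean, numeric(1))
  vars <- vapply(halves, stats::var, numeric(1))
  W <- mean(vars)
  B <- n * stats::var(means)
  if (W == 0) return(if (B == 0) 1 else Inf)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Joint log density of the DHGLM
#'
#' Evaluates log prior + log latent density + log likelihood for a full
#' set of parameter and (zero-mean) latent values, exactly matching the
#' model sampled by [dhglm()]. Used for validating the sampler against a
#' brute-force per-term oracle.
#'
#' @param design a [dhglm_data()] object.
#' @param params named list with elements `beta` (named vector over mean
#'   part fixed effects, cluster-level then observation-level), `gamma`
#'   (dispersion part), `sd_year`, `sd_sys` (length-2 `c(mean, disp)`),
#'   `r_sys`, and either habitat-specific `sd_clust_m`, `sd_clust_d`,
#'   `r_clust` (each length-2 `c(forest, urban)`) or scalars of the same
#'   names when `design$hetero` is `FALSE`.
#' @param latent named list with `a_year` (length nY), `u_sys` (nS x 2
#'   matrix) and `u_clust` (nC x 2 matrix), all zero-mean deviations.
#' @param components if `TRUE` return the `data`, `latent` and `prior`
#'   terms separately along with `total`.
#' @return scalar log density, or a list of components.
#' @export
dhglm_log_density <- function(design, params, latent, components = FALSE) {
  d <- design
  beta <- params$beta[c(colnames(d$Xc_m), colnames(d$Xo_m))]
  gamma <- params$gamma[c(colnames(d$Xc_d), colnames(d$Xo_d))]
  if (any(is.na(beta)) || any(is.na(gamma)))
    stop("params$beta/params$gamma must cover all design columns")

  pc_m <- ncol(d$Xc_m); pc_d <- ncol(d$Xc_d)
  eta_c_m <- drop(d$Xc_m %*% beta[seq_len(pc_m)])
  eta_c_d <- drop(d$Xc_d %*% gamma[seq_len(pc_d)])
  mu <- eta_c_m[d$clust_idx] +
    latent$a_year[d$year_idx] +
    latent$u_sys[d$csys_idx[d$clust_idx], 1] +
    latent$u_clust[d$clust_idx, 1]
  log_sd <- eta_c_d[d$clust_idx] +
    latent$u_sys[d$csys_idx[d$clust_idx], 2] +
    latent$u_clust[d$clust_idx, 2]
  if (ncol(d$Xo_m) > 0)
    mu <- mu + drop(d$Xo_m %*% beta[-seq_len(pc_m)])
  if (ncol(d$Xo_d) > 0)
    log_sd <- log_sd + drop(d$Xo_d %*% gamma[-seq_len(pc_d)])

  lp_data <- if (d$n > 0)
    sum(stats::dnorm(d$y, mu, exp(log_sd), log = TRUE)) else 0
  if (!is.finite(lp_data))
    stop("non-finite log density in the data term")

  lp_latent <- sum(stats::dnorm(latent$a_year, 0, params$sd_year,
                                log = TRUE)) +
    sum(vapply(seq_len(d$nS), function(s)
      uv_dbinorm(latent$u_sys[s, ], params$sd_sys[1], params$sd_sys[2],
                 params$r_sys), numeric(1)))
  if (d$hetero) {
    hi <- d$chab + 1L
    lp_latent <- lp_latent + sum(vapply(seq_len(d$nC), function(cc)
      uv_dbinorm(latent$u_clust[cc, ], params$sd_clust_m[hi[cc]],
                 params$sd_clust_d[hi[cc]], params$r_clust[hi[cc]]),
      numeric(1)))
  } else {
    lp_latent <- lp_latent + sum(vapply(seq_len(d$nC), function(cc)
      uv_dbinorm(latent$u_clust[cc, ], params$sd_clust_m[1],
                 params$sd_clust_d[1], params$r_clust[1]), numeric(1)))
  }
  if (!is.finite(lp_latent))
    stop("non-finite log density in the latent term")

  sds <- c(params$sd_year, params$sd_sys, params$sd_clust_m,
           params$sd_clust_d)
  cors <- c(params$r_sys, params$r_clust)
  lp_prior <- sum(stats::dnorm(c(beta, gamma), 0, 1, log = TRUE)) +
    sum(uv_dhalfnorm(sds)) + sum(uv_dlkj2(cors))
  if (!is.finite(lp_prior))
    stop("non-finite log density in the prior term")

  if (components)
    list(data = lp_data, latent = lp_latent, prior = lp_prior,
         total = lp_data + lp_latent + lp_prior)
  else lp_data + lp_latent + lp_prior
}

# bivariate normal log density with zero mean
uv_dbinorm <- function(u, s1, s2, r) {
  z1 <- u[1] / s1; z2 <- u[2] / s2
  q <- (z1^2 - 2 * r * z1 * z2 + z2^2) / (1 - r^2)
  -log(2 * pi) - log(s1 * s2 * sqrt(1 - r^2)) - q / 2
}

# half-Normal(0,1) log density
uv_dhalfnorm <- function(x) {
  ifelse(x >= 0, log(2) + stats::dnorm(x, 0, 1, log = TRUE), -Inf)
}

# LKJ(df = 2) log density of a 2x2 correlation, via (r+1)/2 ~ Beta(2,2)
uv_dlkj2 <- function(r) {
  stats::dbeta((r + 1) / 2, 2, 2, log = TRUE) - log(2)
}

# --- JAGS model assembly ----------------------------------------------------

uv_jags_spec <- function(design, homoscedastic = FALSE) {
  d <- design
  if (any(d$Xc_m[, 1] != 1) || any(d$Xc_d[, 1] != 1))
    stop("the first column of each cluster-level design must be the ",
         "intercept")
  # coefficients whose covariate column is all zero (constant covariates
  # centred by build_design) are detached from the likelihood and sampled
  # from their Normal(0,1) prior directly: the posterior is identical and
  # the block samplers keep non-singular design blocks
  keep <- function(X) colSums(X != 0) > 0
  km <- keep(d$Xc_m); kd <- keep(d$Xc_d)
  kom <- keep(d$Xo_m); kod <- keep(d$Xo_d)
  Xc_m <- d$Xc_m[, km, drop = FALSE]
  Xc_d <- d$Xc_d[, kd, drop = FALSE]
  Xo_m <- d$Xo_m[, kom, drop = FALSE]
  Xo_d <- d$Xo_d[, kod, drop = FALSE]
  prior_only <- c(colnames(d$Xc_m)[!km], colnames(d$Xo_m)[!kom],
                  if (!homoscedastic) c(colnames(d$Xc_d)[!kd],
                                        colnames(d$Xo_d)[!kod]))
  pOm <- ncol(Xo_m); pOd <- ncol(Xo_d)

  data <- list(nY = d$nY, nS = d$nS, nC = d$nC,
               csys = d$csys_idx, Xc_m = Xc_m, Xc_d = Xc_d,
               pCm = ncol(Xc_m), pCd = ncol(Xc_d))
  if (d$n > 0) {
    data$y <- d$y; data$n <- d$n
    data$year <- d$year_idx; data$clust <- d$clust_idx
    if (pOm > 0) data$Xo_m <- Xo_m
    if (pOd > 0 && !homoscedastic) data$Xo_d <- Xo_d
  }
  if (d$hetero) {
    if (homoscedastic) data$hab1 <- d$chab + 1L
    if (!homoscedastic) {
      fidx <- which(d$chab == 0L); uidx <- which(d$chab == 1L)
      if (length(fidx) < 2 || length(uidx) < 2)
        stop("habitat-specific cluster variances need at least 2 clusters ",
             "per habitat; use an ISA mode otherwise")
      data$fidx <- fidx; data$uidx <- uidx
      data$nF <- length(fidx); data$nU <- length(uidx)
    }
  }
  if (homoscedastic) { data$Xc_d <- NULL; data$pCd <- NULL }

  mu_extra <- if (pOm > 0) " + inprod(Xo_m[i,], beta_o)" else ""
  sd_extra <- if (pOd > 0 && !homoscedastic)
    " + inprod(Xo_d[i,], gamma_o)" else ""

  lik <- if (d$n > 0) paste0(
    "  for (i in 1:n) {\n",
    "    mu[i] <- u_cl[clust[i],1] + a_year[year[i]]", mu_extra, "\n",
    if (homoscedastic)
      "    y[i] ~ dnorm(mu[i], exp(-2*gamma_c[1]))\n" else
      paste0("    log_sd[i] <- u_cl[clust[i],2]", sd_extra, "\n",
             "    y[i] ~ dnorm(mu[i], exp(-2*log_sd[i]))\n"),
    "  }\n") else ""

  po_priors <- paste0(vapply(prior_only, function(nm)
    paste0("  ", nm, " ~ dnorm(0,1)\n"), character(1)), collapse = "")

  if (homoscedastic) {
    # system effects are centred on the intercept (conjugate updates)
    groups <- paste0(
      "  for (t in 1:nY) { a_year[t] ~ dnorm(0, pow(sd_year,-2)) }\n",
      "  for (s in 1:nS) { a_sys[s] ~ dnorm(beta_c[1], pow(sd_sys_m,-2)) }\n",
      "  for (c in 1:nC) {\n",
      "    cm1[c] <- inprod(Xc_m[c,2:pCm], beta_c[2:pCm]) + a_sys[csys[c]]\n",
      if (d$hetero)
        "    u_cl[c,1] ~ dnorm(cm1[c], pow(sd_cl_m[hab1[c]],-2))\n" else
        "    u_cl[c,1] ~ dnorm(cm1[c], pow(sd_cl_m1,-2))\n",
      "  }\n")
    sd_priors <- paste0(
      "  sd_year ~ dnorm(0,1) T(0,)\n  sd_sys_m ~ dnorm(0,1) T(0,)\n",
      if (d$hetero)
        "  sd_cl_m[1] ~ dnorm(0,1) T(0,)\n  sd_cl_m[2] ~ dnorm(0,1) T(0,)\n"
      else "  sd_cl_m1 ~ dnorm(0,1) T(0,)\n",
      "  gamma_c[1] ~ dnorm(0,1)\n")
    fe_priors <- "  for (j in 1:pCm) { beta_c[j] ~ dnorm(0,1) }\n"
    if (pOm > 0)
      fe_priors <- paste0(fe_priors,
        "  for (j in 1:", pOm, ") { beta_o[j] ~ dnorm(0,1) }\n")
    model <- paste0("model {\n", lik, groups, fe_priors, sd_priors,
                    po_priors, "}\n")
    params <- c("beta_c", if (pOm > 0) "beta_o", "gamma_c",
                "sd_year", "sd_sys_m",
                if (d$hetero) "sd_cl_m" else "sd_cl_m1", prior_only)
    latents <- c("a_year", "a_sys", "u_cl")
    spec <- list(model = model, data = data, params = params,
                 latents = latents, design = d,
                 cols = list(cm = colnames(Xc_m), cd = "gamma_0",
                             om = colnames(Xo_m), od = character(0),
                             prior_only = prior_only),
                 homoscedastic = TRUE)
    spec$param_names <- uv_param_names(spec)
    spec$latent_names <- uv_latent_names(spec)
    return(spec)
  }

  # hierarchical centring throughout: system pairs are centred on the two
  # part intercepts, cluster pairs on the full cluster-level predictors
  groups <- paste0(
    "  for (t in 1:nY) { a_year[t] ~ dnorm(0, pow(sd_year,-2)) }\n",
    "  m_sys[1] <- beta_c[1]\n  m_sys[2] <- gamma_c[1]\n",
    "  for (s in 1:nS) { u_sys[s,1:2] ~ dmnorm(m_sys, Om_sys) }\n",
    "  for (c in 1:nC) {\n",
    "    cm[c,1] <- inprod(Xc_m[c,2:pCm], beta_c[2:pCm]) + u_sys[csys[c],1]\n",
    "    cm[c,2] <- inprod(Xc_d[c,2:pCd], gamma_c[2:pCd]) + u_sys[csys[c],2]\n",
    if (d$hetero) paste0(
      "  }\n",
      "  for (f in 1:nF) {\n",
      "    u_cl[fidx[f],1:2] ~ dmnorm(cm[fidx[f],1:2], Om_clF)\n  }\n",
      "  for (u in 1:nU) {\n",
      "    u_cl[uidx[u],1:2] ~ dmnorm(cm[uidx[u],1:2], Om_clU)\n  }\n") else
      paste0("    u_cl[c,1:2] ~ dmnorm(cm[c,1:2], Om_cl1)\n",
             "  }\n"))

  covs <- paste0(
    "  Sig_sys[1,1] <- pow(sd_sys_m,2)\n",
    "  Sig_sys[2,2] <- pow(sd_sys_d,2)\n",
    "  Sig_sys[1,2] <- r_sys*sd_sys_m*sd_sys_d\n",
    "  Sig_sys[2,1] <- Sig_sys[1,2]\n",
    "  Om_sys <- inverse(Sig_sys)\n",
    if (d$hetero) paste0(
      "  Sig_cl[1,1,1] <- pow(sd_cl_m[1],2)\n",
      "  Sig_cl[2,2,1] <- pow(sd_cl_d[1],2)\n",
      "  Sig_cl[1,2,1] <- r_cl[1]*sd_cl_m[1]*sd_cl_d[1]\n",
      "  Sig_cl[2,1,1] <- Sig_cl[1,2,1]\n",
      "  Sig_cl[1,1,2] <- pow(sd_cl_m[2],2)\n",
      "  Sig_cl[2,2,2] <- pow(sd_cl_d[2],2)\n",
      "  Sig_cl[1,2,2] <- r_cl[2]*sd_cl_m[2]*sd_cl_d[2]\n",
      "  Sig_cl[2,1,2] <- Sig_cl[1,2,2]\n",
      "  Om_clF <- inverse(Sig_cl[1:2,1:2,1])\n",
      "  Om_clU <- inverse(Sig_cl[1:2,1:2,2])\n") else paste0(
      "  Sig_cl1[1,1] <- pow(sd_cl_m1,2)\n",
      "  Sig_cl1[2,2] <- pow(sd_cl_d1,2)\n",
      "  Sig_cl1[1,2] <- r_cl1*sd_cl_m1*sd_cl_d1\n",
      "  Sig_cl1[2,1] <- Sig_cl1[1,2]\n",
      "  Om_cl1 <- inverse(Sig_cl1)\n"))

  fe_priors <- paste0(
    "  for (j in 1:pCm) { beta_c[j] ~ dnorm(0,1) }\n",
    "  for (j in 1:pCd) { gamma_c[j] ~ dnorm(0,1) }\n",
    if (pOm > 0) paste0("  for (j in 1:", pOm,
                        ") { beta_o[j] ~ dnorm(0,1) }\n") else "",
    if (pOd > 0) paste0("  for (j in 1:", pOd,
                        ") { gamma_o[j] ~ dnorm(0,1) }\n") else "")

  sd_priors <- paste0(
    "  sd_year ~ dnorm(0,1) T(0,)\n",
    "  sd_sys_m ~ dnorm(0,1) T(0,)\n  sd_sys_d ~ dnorm(0,1) T(0,)\n",
    "  br_sys ~ dbeta(2,2)\n  r_sys <- 2*br_sys - 1\n",
    if (d$hetero) paste0(
      "  sd_cl_m[1] ~ dnorm(0,1) T(0,)\n  sd_cl_m[2] ~ dnorm(0,1) T(0,)\n",
      "  sd_cl_d[1] ~ dnorm(0,1) T(0,)\n  sd_cl_d[2] ~ dnorm(0,1) T(0,)\n",
      "  br_f ~ dbeta(2,2)\n  r_cl[1] <- 2*br_f - 1\n",
      "  br_u ~ dbeta(2,2)\n  r_cl[2] <- 2*br_u - 1\n") else paste0(
      "  sd_cl_m1 ~ dnorm(0,1) T(0,)\n  sd_cl_d1 ~ dnorm(0,1) T(0,)\n",
      "  br_c ~ dbeta(2,2)\n  r_cl1 <- 2*br_c - 1\n"))

  model <- paste0("model {\n", lik, groups, covs, fe_priors, sd_priors,
                  po_priors, "}\n")
  params <- c("beta_c", if (pOm > 0) "beta_o",
              "gamma_c", if (pOd > 0) "gamma_o",
              "sd_year", "sd_sys_m", "sd_sys_d", "r_sys",
              if (d$hetero) c("sd_cl_m", "sd_cl_d", "r_cl") else
                c("sd_cl_m1", "sd_cl_d1", "r_cl1"), prior_only)
  latents <- c("a_year", "u_sys", "u_cl")
  spec <- list(model = model, data = data, params = params,
               latents = latents, design = d,
               cols = list(cm = colnames(Xc_m), cd = colnames(Xc_d),
                           om = colnames(Xo_m), od = colnames(Xo_d),
                           prior_only = prior_only),
               homoscedastic = FALSE)
  spec$param_names <- uv_param_names(spec)
  spec$latent_names <- uv_latent_names(spec)
  spec
}

# central initial values for every stochastic node of the model
uv_jags_inits <- function(spec) {
  d <- spec$design
  cl <- spec$cols
  ini <- list(beta_c = rep(0, length(cl$cm)),
              a_year = rep(0, d$nY),
              sd_year = 0.5, sd_sys_m = 0.5)
  if (length(cl$om) > 0) ini$beta_o <- rep(0, length(cl$om))
  for (nm in cl$prior_only) ini[[nm]] <- 0
  if (spec$homoscedastic) {
    ini$gamma_c <- 0
    ini$a_sys <- rep(0, d$nS)
    ini$u_cl <- matrix(0, d$nC, 1)
    if (d$hetero) ini$sd_cl_m <- c(0.5, 0.5) else ini$sd_cl_m1 <- 0.5
    return(ini)
  }
  ini$gamma_c <- rep(0, length(cl$cd))
  if (length(cl$od) > 0) ini$gamma_o <- rep(0, length(cl$od))
  ini$sd_sys_d <- 0.5
  ini$br_sys <- 0.5
  ini$u_sys <- matrix(0, d$nS, 2)
  ini$u_cl <- matrix(0, d$nC, 2)
  if (d$hetero) {
    ini$sd_cl_m <- c(0.5, 0.5); ini$sd_cl_d <- c(0.5, 0.5)
    ini$br_f <- 0.5; ini$br_u <- 0.5
  } else {
    ini$sd_cl_m1 <- 0.5; ini$sd_cl_d1 <- 0.5; ini$br_c <- 0.5
  }
  ini
}

# coda column keys for a monitored vector: JAGS drops the index when the
# vector has length 1
uv_vec_keys <- function(base, len) {
  if (len == 1L) base else paste0(base, "[", seq_len(len), "]")
}

# canonical names for the monitored model parameters, in JAGS column order
uv_param_names <- function(spec) {
  d <- spec$design
  cl <- spec$cols
  ren <- c()
  ren[uv_vec_keys("beta_c", length(cl$cm))] <- cl$cm
  if (length(cl$om) > 0)
    ren[uv_vec_keys("beta_o", length(cl$om))] <- cl$om
  if (spec$homoscedastic) {
    ren["gamma_c"] <- "gamma_0"
    ren["sd_year"] <- "sd_year"; ren["sd_sys_m"] <- "sd_sys_m"
    if (d$hetero) {
      ren["sd_cl_m[1]"] <- "sd_clust_m_forest"
      ren["sd_cl_m[2]"] <- "sd_clust_m_urban"
    } else ren["sd_cl_m1"] <- "sd_clust_m"
    ren[cl$prior_only] <- cl$prior_only
    return(ren)
  }
  ren[uv_vec_keys("gamma_c", length(cl$cd))] <- cl$cd
  if (length(cl$od) > 0)
    ren[uv_vec_keys("gamma_o", length(cl$od))] <- cl$od
  ren["sd_year"] <- "sd_year"
  ren["sd_sys_m"] <- "sd_sys_m"; ren["sd_sys_d"] <- "sd_sys_d"
  ren["r_sys"] <- "r_sys"
  if (d$hetero) {
    ren["sd_cl_m[1]"] <- "sd_clust_m_forest"
    ren["sd_cl_m[2]"] <- "sd_clust_m_urban"
    ren["sd_cl_d[1]"] <- "sd_clust_d_forest"
    ren["sd_cl_d[2]"] <- "sd_clust_d_urban"
    ren["r_cl[1]"] <- "r_forest"
    ren["r_cl[2]"] <- "r_urban"
  } else {
    ren["sd_cl_m1"] <- "sd_clust_m"
    ren["sd_cl_d1"] <- "sd_clust_d"
    ren["r_cl1"] <- "r_clust"
  }
  ren[cl$prior_only] <- cl$prior_only
  ren
}

uv_latent_names <- function(spec) {
  d <- spec$design
  ren <- c()
  ren[uv_vec_keys("a_year", d$nY)] <-
    paste0("a_year[", seq_len(d$nY), "]")
  if (spec$homoscedastic) {
    ren[uv_vec_keys("a_sys", d$nS)] <-
      paste0("u_sys[", seq_len(d$nS), ",1]")
    ren[paste0("u_cl[", seq_len(d$nC), ",1]")] <-
      paste0("u_clust[", seq_len(d$nC), ",1]")
    return(ren)
  }
  for (k in 1:2) {
    ren[paste0("u_sys[", seq_len(d$nS), ",", k, "]")] <-
      paste0("u_sys[", seq_len(d$nS), ",", k, "]")
    ren[paste0("u_cl[", seq_len(d$nC), ",", k, "]")] <-
      paste0("u_clust[", seq_len(d$nC), ",", k, "]")
  }
  ren
}

uv_rename_draws <- function(draws, spec) {
  ren <- c(uv_param_names(spec), uv_latent_names(spec))
  coda::as.mcmc.list(lapply(draws, function(ch) {
    cn <- colnames(ch)
    hit <- cn %in% names(ren)
    cn[hit] <- ren[cn[hit]]
    colnames(ch) <- cn
    ch
  }))
}

# posterior-mean linear predictors mu_i and sigma_i (needs latent draws)
uv_linpred <- function(fit) {
  d <- fit$design
  if (!length(fit$latent_names))
    stop("fit was run with monitor_latent = FALSE")
  m <- as.matrix(fit$draws)
  est <- colMeans(m)
  beta <- est[c(colnames(d$Xc_m), colnames(d$Xo_m))]
  a_year <- est[paste0("a_year[", seq_len(d$nY), "]")]
  # u_clust draws are centred (include the cluster-level linear predictor)
  u1 <- est[paste0("u_clust[", seq_len(d$nC), ",1]")]
  mu <- u1[d$clust_idx] + a_year[d$year_idx]
  if (ncol(d$Xo_m) > 0)
    mu <- mu + drop(d$Xo_m %*% beta[colnames(d$Xo_m)])
  if (fit$homoscedastic) {
    sigma <- rep(exp(est[["gamma_0"]]), d$n)
  } else {
    u2 <- est[paste0("u_clust[", seq_len(d$nC), ",2]")]
    log_sd <- u2[d$clust_idx]
    if (ncol(d$Xo_d) > 0)
      log_sd <- log_sd + drop(d$Xo_d %*%
                                est[colnames(d$Xo_d)])
    sigma <- exp(log_sd)
  }
  list(mu = as.numeric(mu), sigma = as.numeric(sigma))
}
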