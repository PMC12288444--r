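# independent per-term oracle for the joint log density, written as plain
# loops with its own bivariate-normal formula (solve + determinant)
oracle_log_density <- function(d, params, latent) {
  dbi <- function(u, s1, s2, r) {
    S <- matrix(c(s1^2, r * s1 * s2, r * s1 * s2, s2^2), 2)
    -log(2 * pi) - 0.5 * log(det(S)) -
      0.5 * drop(t(u) %*% solve(S) %*% u)
  }
  beta <- params$beta; gamma <- params$gamma
  lp <- 0
  for (i in seq_len(d$n)) {
    ci <- d$clust_idx[i]; si <- d$csys_idx[ci]
    mu <- sum(d$Xc_m[ci, ] * beta[colnames(d$Xc_m)]) +
      latent$a_year[d$year_idx[i]] + latent$u_sys[si, 1] +
      latent$u_clust[ci, 1]
    ls <- sum(d$Xc_d[ci, ] * gamma[colnames(d$Xc_d)]) +
      latent$u_sys[si, 2] + latent$u_clust[ci, 2]
    if (ncol(d$Xo_m) > 0)
      mu <- mu + sum(d$Xo_m[i, ] * beta[colnames(d$Xo_m)])
    if (ncol(d$Xo_d) > 0)
      ls <- ls + sum(d$Xo_d[i, ] * gamma[colnames(d$Xo_d)])
    lp <- lp + dnorm(d$y[i], mu, exp(ls), log = TRUE)
  }
  for (t in seq_len(d$nY))
    lp <- lp + dnorm(latent$a_year[t], 0, params$sd_year, log = TRUE)
  for (s in seq_len(d$nS))
    lp <- lp + dbi(latent$u_sys[s, ], params$sd_sys[1], params$sd_sys[2],
                   params$r_sys)
  for (cc in seq_len(d$nC)) {
    h <- d$chab[cc] + 1
    lp <- lp + dbi(latent$u_clust[cc, ], params$sd_clust_m[h],
                   params$sd_clust_d[h], params$r_clust[h])
  }
  for (b in c(beta, gamma)) lp <- lp + dnorm(b, 0, 1, log = TRUE)
  for (s in c(params$sd_year, params$sd_sys, params$sd_clust_m,
              params$sd_clust_d))
    lp <- lp + log(2) + dnorm(s, 0, 1, log = TRUE)
  for (r in c(params$r_sys, params$r_clust))
    lp <- lp + dbeta((r + 1) / 2, 2, 2, log = TRUE) - log(2)
  lp
}

tiny_design <- function(n = 20, seed = 13) {
  set.seed(seed)
  nC <- 4; nS <- 2; nY <- 3
  Xc_m <- cbind(beta_0 = rep(1, nC), beta_hab = c(0, 1, 0, 1),
                beta_lat = rnorm(nC))
  Xc_d <- cbind(gamma_0 = rep(1, nC), gamma_hab = c(0, 1, 0, 1),
                gamma_het = rnorm(nC))
  dhglm_data(y = rnorm(n), year_idx = sample(nY, n, TRUE),
             clust_idx = rep_len(1:nC, n), csys_idx = c(1L, 1L, 2L, 2L),
             chab = c(0L, 1L, 0L, 1L),
             Xo_m = matrix(rbinom(n, 1, 0.5), n, 1,
                           dimnames = list(NULL, "beta_sex")),
             Xo_d = matrix(numeric(0), n, 0),
             Xc_m = Xc_m, Xc_d = Xc_d, hetero = TRUE)
}

tiny_params <- function(seed = 3) {
  set.seed(seed)
  list(beta = c(beta_0 = 0.2, beta_hab = -0.3, beta_lat = 0.5,
                beta_sex = 0.54),
       gamma = c(gamma_0 = -0.5, gamma_hab = 0.1, gamma_het = -0.01),
       sd_year = 0.2, sd_sys = c(0.9, 0.5), r_sys = -0.1,
       sd_clust_m = c(0.25, 0.48), sd_clust_d = c(0.24, 0.24),
       r_clust = c(-0.3, -0.3))
}

tiny_latent <- function(d, seed = 5) {
  set.seed(seed)
  list(a_year = rnorm(d$nY, 0, 0.2),
       u_sys = matrix(rnorm(d$nS * 2, 0, 0.4), d$nS, 2),
       u_clust = matrix(rnorm(d$nC * 2, 0, 0.3), d$nC, 2))
}

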