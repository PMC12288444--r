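# urbanvar

Phenotypic variance partitioning along replicated urban gradients with
double-hierarchical Gaussian models (DHGLMs).

## The problem

Urbanisation changes not only the *average* phenotype of wild populations
(urban great and blue tits are smaller and lay earlier than forest birds)
but also how much individuals *vary* — and that variation can sit at
different spatial scales. Given long-term nest-box records from many study
systems (a city plus its surrounding forest), three questions arise:

1. Do urban subpopulations differentiate more from each other in their
   mean trait than forest subpopulations (among-subpopulation
   heterogeneity)?
2. Do urban subpopulations contain more trait variation internally
   (within-subpopulation heterogeneity)?
3. Do urban subpopulations differ more *in the amount of variation they
   contain* (heterogeneity in heterogeneity)?

`urbanvar` implements the full analysis pipeline for these questions, for
two species (great tit *Parus major*, blue tit *Cyanistes caeruleus*) and
three traits (adult tarsus length, nestling tarsus length, lay date):

- **Spatial clustering** of nest boxes into subpopulations ("clusters"):
  connected components of the graph joining boxes within 300 m geodesic
  distance, keeping components with at least 5 boxes.
- **Urbanisation covariates** per cluster: impervious surface proportion
  (ISA) in 100 m and 1000 m buffers, land-cover Shannon diversity, from
  plain-text toy rasters.
- **Preprocessing**: tarsus method conversion, trait-specific outlier
  windows, first-clutch selection (within 30 days of the group's first lay
  date), one observation per individual (mean tarsus per adult, one random
  nestling per brood, first clutch per female), Z-transformation.
- **The DHGLM**, a Bayesian location–scale mixed model fitted with JAGS:

  y_i ~ N(mu_i, sigma_i^2)

  mu_i      = x_i' beta  + a_year(i) + a_sys(i) + a_clust(i)

  log sigma_i = z_i' gamma + b_sys(i) + b_clust(i)

  System pairs (a_sys, b_sys) and cluster pairs (a_clust, b_clust) are
  bivariate normal with mean–dispersion correlations; cluster pairs get
  habitat-specific (urban vs. forest) standard deviations. The three
  target quantities are the habitat-specific among-cluster variances in
  the mean part (question 1), the urban coefficient in the dispersion part
  (question 2, a log-scale effect on the residual SD), and the
  habitat-specific among-cluster variances in the dispersion part
  (question 3). Priors: N(0,1) fixed effects, half-N(0,1) random-effect
  SDs, LKJ(2) correlations.
- **Posterior summaries**: shortest-interval HPDIs (95% and 50%),
  probability of direction (pd), the evidence rules (HPDI excludes zero →
  evidence; pd > 0.90 → weak), per-draw urban-minus-forest variance
  contrasts, and back-transformed residual SDs
  (`100 * (exp(gamma_hab) - 1)` percent change).
- **A synthetic-data generator** that simulates complete gradient studies
  (landscape, rasters, nest boxes, observations) from the same generative
  model, with the fitted estimates of the six species × trait analyses as
  default parameters — so the whole pipeline is testable without field
  data.

## Worked example

```r
library(urbanvar)

# simulate a replicated urban gradient study at the default desk scale
scn <- sim_scenario(species = "great_tit", trait = "adult_tarsus")
sim <- simulate_observations(scn, seed = 7, units = "model")

# fit the DHGLM (reduced protocol for the example)
fit <- dhglm(sim$design,
             dhglm_control(chains = 2, iter = 2000, warmup = 1000,
                           thin = 1, adapt = 500, seed = 3))
fit
#> Double-hierarchical Gaussian model
#>   great_tit adult_tarsus, urbanisation mode 'categorical'
#>   2000 obs, 40 clusters, 4 systems, 5 years
#>   2 chains x 2000 iter (warmup 1000, thin 1): 2000 draws, 5.6 s
#>   convergence: max split-Rhat 1.032, min ESS 263 (CHECK)
#>   posterior means:
#>            beta_0          beta_hab          beta_lat          beta_sex
#>            -0.051            -0.031             0.509             0.519
#>           gamma_0         gamma_hab         gamma_het         gamma_lat
#>            -0.259            -0.216             0.044             0.017
#>   ...

habitat_variance_contrast(fit, "cluster_mean")
#> Among-cluster variance contrast (cluster_mean):
#>   urban 0.354 vs forest 0.099 (ratio of means 3.58)
#>   urban - forest: 0.255 [0.013, 0.550], pd(positive) = 0.988 (evidence)
```

The contrast says: among-cluster variance in mean tarsus length is about
3.6 times higher across urban clusters than forest clusters in this
simulated study (the generating values, taken from the fitted great tit
estimates, have ratio 0.234/0.056 ≈ 4.2), the posterior probability that
the difference is positive is 0.99, and its 95% HPDI excludes zero —
"evidence" under the reporting rules. The short example chains flag their
own convergence (`CHECK`); the default `dhglm_control()` runs the full
protocol (4 chains × 10,000 iterations, warm-up 6,000, thinning 4 → 4,000
retained draws).

The same analysis runs end to end from one configuration with
`run_pipeline()`, which writes clusters, filter reports, draws,
diagnostics and a summary table into an artifact directory and skips
already-completed stages on rerun.

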