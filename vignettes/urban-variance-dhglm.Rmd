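---
title: "Partitioning phenotypic variation along urban gradients: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Partitioning phenotypic variation along urban gradients: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical model behind `urbanvar`, the
choices that shape its implementation, what the synthetic-data generator
does and does not emulate, and the package's known limitations. Code
chunks are shown but not evaluated at build time; every number quoted
here is computed by the package's test suite or by
`scripts/acceptance.R`.

## 1. The model

`urbanvar` fits a double-hierarchical Gaussian model (DHGLM): a Gaussian
mixed model in which the *residual standard deviation* is itself a
mixed model on the log scale. For observation $i$ in year $t(i)$, study
system $s(i)$ and nest-box cluster $c(i)$:

$$y_i \sim \mathcal{N}(\mu_i,\ \sigma_i^2)$$
$$\mu_i = \mathbf{x}_i^\top\boldsymbol\beta + a_{t(i)} + a^{(s)}_{s(i)} + a^{(c)}_{c(i)}$$
$$\log \sigma_i = \mathbf{z}_i^\top\boldsymbol\gamma + b^{(s)}_{s(i)} + b^{(c)}_{c(i)}$$

The response is the Z-transformed trait (adult tarsus, nestling tarsus
or lay date, analysed separately per species). The mean part carries an
intercept, the urbanisation term, standardised cluster mean latitude and
a trait-specific observation covariate (sex for adult tarsus, chick age
for nestling tarsus, none for lay date). The dispersion part carries an
intercept, the urbanisation term, standardised land-cover Shannon
diversity, latitude, cluster area and number of years studied, plus sex
(adult tarsus) or female age (lay date).

Random effects: year intercepts in the mean part only; system and
cluster effects in both parts, with each level's mean-part and
dispersion-part effects drawn from a bivariate normal with correlation
$r$. Under the categorical urbanisation mode the cluster covariance is
habitat-specific — separate $(\mathrm{sd}, r)$ for forest and urban
clusters. This carries the three scientific targets:

* among-cluster variance in trait means, urban vs. forest
  ($\mathrm{sd}^{(c),2}_{\text{urban}}$ vs.
  $\mathrm{sd}^{(c),2}_{\text{forest}}$, mean part);
* the urban coefficient $\gamma_{\text{hab}}$ on the log residual SD —
  back-transformed, a $100(e^{\gamma_{\text{hab}}}-1)$ percent change in
  within-cluster residual SD;
* among-cluster variance in the log residual SD, urban vs. forest
  (dispersion part).

Under the ISA modes (`isa_100`, `isa_1000`) the habitat dummy is
replaced by standardised impervious-surface proportion and a single
cluster covariance is fitted per part.

Priors, appropriate on the Z scale: $\mathcal{N}(0,1)$ for fixed
effects, half-$\mathcal{N}(0,1)$ for random-effect SDs, LKJ with
shape 2 for each $2\times2$ correlation matrix. For a $2\times2$ matrix
the LKJ(2) prior is exactly $(r+1)/2 \sim \mathrm{Beta}(2,2)$, which is
how it is implemented.

### Dispersion link

The dispersion part models the log of the residual **SD**, not the
variance. This choice is what makes the back-transformation
$100(e^{\gamma_{\text{hab}}}-1)$ reproduce the reported percent
increases (e.g. a coefficient of 0.109 gives +11.5%, 0.223 gives +25%);
`back_transform_dispersion()` also returns residual SDs in original
units when given the trait's unstandardised SD.

### Reporting rules

`summary()` on a fit reports, per term: posterior mean and median, 95%
and 50% HPDIs (shortest contiguous window on the sorted draws), the
probability of direction (pd, ties at zero split evenly so
$pd^+ + pd^- = 1$), and the evidence flags: fixed effects and
correlations are flagged when the 95% HPDI excludes zero; random-effect
SDs when the interval sits above 0.001. Effects with an interval
overlapping zero but pd > 0.90 are classified "weak"; otherwise "none".
Variance summaries are computed per draw as SD² and then summarised, so
the SD→variance nonlinearity is respected. Whether a reader prefers the
SD or the variance scale for the random-effect point estimates, both are
emitted.

## 2. Sampling

The model is fitted with JAGS through `rjags`. Three implementation
choices matter and were validated on parameter-recovery experiments (not
tuned to them):

1. **Hierarchical centring.** Cluster pairs are drawn around their
   cluster-level linear predictors and system pairs around the two part
   intercepts. Under conditional (Gibbs/slice) sampling, centring mixes
   far better than the non-centred form whenever groups are
   well-informed by data, which is the case at every level here; the
   non-centred form is an HMC-specific remedy and mixed very poorly in
   JAGS (effective sample sizes of tens instead of hundreds). The joint
   density is identical either way.
2. **The `glm` module** is loaded so JAGS can block-sample the conjugate
   normal sub-graph (fixed effects, year effects, system pairs and the
   mean-part cluster effects jointly). Without it, the softly-identified
   common level shared between the year effects and the intercept mixes
   by slow per-node diffusion. The habitat-specific cluster covariances
   are written as two separate loops with named $2\times2$ precision
   matrices; an equivalent formulation through a 3-d precision array
   crashed the module's block factory.
3. **Central initial values** (latent effects at 0, SDs at 0.5,
   correlations at 0). Initialising latents from the prior occasionally
   produced dispersion values extreme enough that the block sampler's
   normal-equation solve overflowed ("not positive definite"); central
   starts remove this entirely. Chains still differ through their
   per-chain RNG streams, and identical seeds reproduce draws exactly.

Coefficients whose covariate column is constant in a given dataset
(possible in balanced synthetic designs, e.g. every cluster studied the
same number of years) are centred to zero by `build_design()` and
sampled from their prior as detached nodes: the posterior is unchanged
and the design blocks stay non-singular.

The default `dhglm_control()` follows the study protocol: 4 chains ×
10,000 iterations, warm-up 6,000 (the first 1,000 as sampler
adaptation), thinning 4, retaining 4,000 draws. Convergence is checked
with split-$\hat R$ (each chain halved) and effective sample size per
parameter; the operational gate is $\hat R \le 1.01$ and ESS > 400, both
configurable.

## 3. Spatial clustering and environmental metrics

Subpopulations are "clusters": connected components of the graph joining
nest boxes within 300 m *geodesic* distance (WGS84, via
`geosphere::distGeo`), keeping components of at least 5 boxes. Single
linkage is deliberate — transect-shaped box lines chain into one
cluster, which complete linkage would shatter; the threshold and minimum
size are arguments. Cluster labels are assigned by sorting on each
component's smallest box id, so results are independent of input order.
Boxes in undersized components are excluded from analysis.

Cluster area is the convex hull of the member boxes buffered by 150 m
(half the linkage distance), computed in a local plane as the exact
Minkowski sum $A + P r + \pi r^2$ (hull area $A$, perimeter $P$): a
single point gives a disk, a collinear transect a stadium — the area is
always positive. The buffer is configurable. Mean latitude is the
arithmetic mean of member latitudes.

Environmental metrics come from plain-text raster grids: ISA as the mean
of impervious-fraction cells whose centres fall within 100 m / 1000 m of
the cluster centroid (the cell-centre rule is unbiased for fine grids
and makes the result invariant to padding), and land-cover Shannon
diversity $H=-\sum p_i\ln p_i$ (natural log; the index is standardised
before entering the model, so the base cannot affect fits) over classes
within the 1000 m buffer.

## 4. Preprocessing

The chain is fixed and audited: species/trait subset → cluster
membership → tarsus method conversion (per-method linear calibrations
onto Svensson's Alternative; unknown methods are dropped and logged) →
closed outlier windows (adult tarsus 12.70–25.49 mm both species;
nestling tarsus 10.2–25.9 mm great tit, 12.11–21 mm blue tit; lay date
75–152 day-of-year, 1 January = 1) → first-clutch selection (lay dates
within 30 days of the species × year × cluster minimum, then each
female's earliest clutch of the season) → deduplication (adults: mean
tarsus per individual; nestlings: one uniformly random nestling per
brood from a dedicated seeded RNG stream that leaves the global RNG
untouched; lay date: each female's first appearance). Every step appends
a filter-report row and the identity
`input rows = final rows + sum(removed)` is enforced by tests.

Standardisation: the response is Z-transformed over the combined
species × trait dataset; continuous cluster-level covariates over
clusters; observation-level covariates over observations; the sample SD
uses the $n-1$ denominator. The centring pairs are stored for
back-transformation to mm / days.

## 5. The synthetic-data generator

`simulate_observations()` runs the generative model forward: it builds a
landscape (`simulate_landscape()`), clusters it with the package's own
clustering rule, extracts environmental covariates from the generated
rasters, and then draws year, system and cluster effects from their
bivariate normals and $y_i \sim \mathcal N(\mu_i, \sigma_i^2)$ exactly
as in the model definition, emitting the full latent truth for recovery
tests.

Default generating parameters are the fitted estimates of the six
species × trait analyses (`default_params()`); the printed random-effect
entries are treated as among-group **variances** — the reported
urban/forest ratios ("four times", "five times") match the printed
values directly only on the variance scale — and their square roots are
used as SDs. Trait centring constants place values in plausible
original units, with scales chosen so that
$e^{\gamma_0} \times \text{scale}$ reproduces the reported forest
residual SDs (0.60/0.49 mm adult, 0.83/0.65 mm nestling, 5.6/6.1 days
lay date). Hypothesis switches equalise the urban and forest cluster SDs
(mean part, H1; dispersion part, H3) or zero the dispersion urban effect
(H2) to create null scenarios.

The default desk scenario is 4 systems × (5 urban + 5 forest) clusters ×
10 boxes × 5 years × 10 individuals per cluster-year ≈ 2,000
observations in 40 clusters — small enough for minutes-scale fitting,
large enough that 95% HPDIs recover the generating values at their
nominal rate (checked over 20 replicates with a binomial test).

Landscape geometry guarantees the intended clusters are exactly
recoverable (120 m grids within clusters, ≥ 700 m gaps between), and
deliberately decorrelates habitat from the other cluster covariates:
cluster rows alternate north/south independently of habitat (latitude ⊥
habitat), and land-cover mosaics vary within habitat (urban disks cycle
2–4 classes; alternate forest clusters are mixed forest/meadow). Without
this the habitat term sits on an exact ridge with latitude and the model
is unidentifiable — a trap worth knowing about in real data too. Urban
ISA is 0.46 on cluster disks against a 0.01 background, matching the
habitat means used as a sanity check.

What the generator does **not** emulate: repeated measures per
individual (it emits one row per analysis unit, so deduplication is a
near no-op on synthetic data and is tested on hand-built fixtures),
second broods, immigration/emigration, pedigree structure, realistic
European geography, temporally autocorrelated climate drivers, or
unbalanced sampling across clusters and years. Passing recovery tests
therefore show the estimator is correct *under the model*, not that the
model is right for any particular field system.

## 6. Numerical choices and degenerate inputs

* HPDI: shortest window of $\lceil p\,n\rceil$ sorted draws; ties
  between equally short windows break toward the lower one. (The coda
  implementation holds $\mathrm{round}(p\,n)+1$ draws; endpoints can
  differ by one order statistic, which tests account for.)
* pd: draws exactly at zero count half toward each direction.
* Percent changes are rounded half-away-from-zero (`round_half_up()`),
  matching how the reported values print.
* Zero-variance covariates: error in `standardize()` (it names the
  covariate); centred-to-zero with a log in `build_design()` (see §2).
* Habitat-specific variances require ≥ 2 clusters per habitat; otherwise
  use an ISA mode.
* Coincident or collinear cluster members: handled by the buffered-hull
  closed form.
* An exact urban/forest tie in a cluster's member habitats is an error
  demanding a manual assignment, not a silent choice.
* Prior-only runs (zero observations) are supported and reproduce the
  priors; they are used to validate the prior implementation.

## 7. Problem sizes used by the test suite

Unit tests run on fixtures of tens of observations. The acceptance-level
checks use: the default desk scenario (≈ 2,000 observations, 40
clusters) fitted 10–20 times at a reduced protocol (2 chains × 2,000
iterations) for recovery and coverage calibration; one fit at 4 chains ×
26,000 iterations (warm-up 6,000, thinning 8, 10,000 retained draws) for
the convergence gate — the protocol shape lengthened because the
year-level scale parameter, with only 5 year levels in the desk
scenario, needs longer chains for a stable split-$\hat R$ under Gibbs
sampling; and a 20,000-observation single simulation for the
forward-simulation check that sample residual-SD ratios converge to
$e^{\gamma_{\text{hab}}}$.

## 8. Known limitations

* The sampler is JAGS: conditional sampling handles this model well at
  desk scale, but very large datasets (10⁴–10⁵ observations × long
  chains) would be slow compared to a gradient-based sampler.
* Within-individual dispersion is out of scope by design: clusters, not
  individuals, are the lowest grouping level, so within-cluster variance
  pools among- and within-individual components.
* No pedigree ("animal model") extension; no model comparison or
  information criteria; no Bayes factors or p-values — inference is by
  HPDI + pd.
* The ISA modes fit a single cluster covariance, so the habitat-specific
  variance contrasts (questions 1 and 3) are only available in
  categorical mode, mirroring the analysis design.
* Real GIS extraction (Europe-wide imperviousness or land-cover
  products) is out of scope; the toy-raster format exists to exercise
  the metric code and the generator.
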