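---
title: "Reaction-norm genetic analysis of heat tolerance: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reaction-norm genetic analysis of heat tolerance: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The scientific problem

Heat stress depresses growth and carcass quality in finishing pigs, and
sires differ genetically in how strongly their offspring respond to thermal
load. `thermonorm` estimates that genetic variation in heat tolerance from
routinely recorded carcass phenotypes (backfat depth cBF, loin depth cLD,
carcass average daily gain cADG), public hourly weather, and pedigree plus
SNP genotype information on sires, and turns the estimates into
selection-relevant outputs: heritability as a function of the environment,
genetic correlations between environments (the signature of
genotype-by-environment interaction), per-sire reaction norms, and rankings
of sires by overall merit and by environmental sensitivity.

# Heat-load covariates

Thermal load is measured by the temperature-humidity index
$$\mathrm{THI} = T - (0.55 - 0.0055\,\mathrm{RH})(T - 14.5),$$
with $T$ the air temperature (&deg;C) and RH the relative humidity on a
0&ndash;100 scale. The index equals $T$ at the 14.5&nbsp;&deg;C pivot and at
saturation; below-pivot temperatures are adjusted upward and above-pivot
temperatures downward as air dries.

THI is evaluated on *hourly* readings and then averaged within
station-days, rather than computed from daily-mean temperature and
humidity. The two orders of operation differ because THI is bilinear in
$T$ and RH; hourly-then-average matches the construction of the index from
quality-controlled hourly station records, and is the package's fixed
choice.

Each animal's lifetime thermal history is summarized over three age
windows, nominally 60&ndash;92, 92&ndash;122 and 122&ndash;152 days of age.
Because the nominal windows share endpoints, the package resolves them as
half-open day-of-age intervals $[60, 92)$, $[92, 122)$, $[122, 152)$; the
windows are configurable. Averaging temperature, humidity and THI over
each window gives nine environmental covariates per animal. A daily value
requires at least one hourly record (configurable), and a window covariate
requires at least 80% of its days to have a daily value; animals failing
that coverage rule are excluded with a logged count rather than silently
zero-filled. Timestamps are taken at face value (no timezone or DST
handling): an hour of mislabelling is negligible against 30-day averages.

# Covariate screening

For every trait &times; covariate combination (27 in the full design), a
fixed-effects model is fitted by ordinary least squares:
$$y = \alpha + CF_i + Par_j + G_k + D_l + \beta\,\phi_1(x) + \varepsilon,$$
with cross-fostering, parity, gender and dam-line factors and the
covariate expressed as a first-order Legendre polynomial on $[-1, 1]$
(order 2 adds $P_2(s) = (3s^2-1)/2$). Combinations are ranked by $R^2$ and
by Gaussian BIC $= -2\hat\ell + k\log n$ (with $k$ counting mean
parameters plus one residual variance); the winners by the two criteria
are flagged separately because they can disagree. Screening fits are
closed-form, so every combination "converges"; convergence bookkeeping is
meaningful only for the Markov-chain stage.

The covariate standardization range (observed min/max in the analysis set)
is persisted by `screen_all()` and reused by the random-regression stage,
so both models see the identical mapping of raw covariate to $s \in
[-1, 1]$.

# Relationship matrices

The among-sire covariance kernel blends pedigree and genomic information:

* **A** &mdash; the numerator relationship matrix by the recursive tabular
  method, with unknown parents treated as unrelated founders and cycles
  rejected by a topological check.
* **G** &mdash; VanRaden method-1 genomic relationships,
  $G = ZZ'/(2\sum_j p_j(1-p_j))$, with dosages centred by $2\hat p_j$
  (frequencies from the genotyped set), monomorphic markers dropped, and
  missing dosages imputed to $2\hat p_j$.
* **H** &mdash; the single-step blend. G is first affinely rescaled so its
  mean diagonal and mean off-diagonal match the genotyped pedigree block
  $A_{22}$, then $G^* = (1-w)G_{\mathrm{scaled}} + wA_{22}$ with default
  $w = 0.05$, and H follows the standard block identity
  ($H_{22} = G^*$, $H_{12} = A_{12}A_{22}^{-1}G^*$,
  $H_{11} = A_{11} + A_{12}A_{22}^{-1}(G^* - A_{22})A_{22}^{-1}A_{21}$).

No published parameterization of this construction was available for the
data the package emulates, so the defaults are the standard ssGBLUP ones
(VanRaden method 1, blend weight 0.05, moment-matching rescaling), all
configurable. With $w = 1$ or nothing genotyped, H reduces to A exactly.

The sampler uses only the principal submatrix of H over the sires with
records (`sire_block()`): marginalizing a jointly Gaussian vector to a
subset is exact, so nothing is lost by not carrying the full pedigree's
effects through the chain.

# The random-regression sire model

The analysis model for a record $y$ of offspring of sire $n$ at
standardized covariate value $\phi_{1m}$ is
$$y = \alpha + CF_i + Par_j + G_k + D_l + \beta\phi_{1m}
      + a_{0n} + a_{1n}\phi_{1m} + b_o + l_p + \varepsilon,$$
with
$(\mathbf a_0, \mathbf a_1)' \sim N(0,\; G_2 \otimes K)$ where $G_2$ is
the $2\times2$ intercept/slope covariance and $K$ the sire block of H
(sires fastest within each coefficient &mdash; the stacking convention is
fixed and documented because "$H \otimes G$" is ambiguous without it);
batch and litter effects iid $N(0, \sigma^2_{ba})$, $N(0, \sigma^2_{li})$;
and residuals heteroskedastic across ten classes cut at the nine deciles
of the environmental covariate, so classes have near-equal size. Records
exactly on a cut point go to the lower class (a fixed, documented
tie-break). The fixed regression $\beta$ multiplies the same standardized
first-order Legendre value as the screening model; the second-order model
(quadratic sire term, $3\times3$ coefficient covariance) is implemented
but order 1 is the default, reflecting the poor convergence such models
show on these traits &mdash; the fitter reports effective-sample-size
diagnostics rather than failing silently.

## Gibbs sampler

Estimation is by a systematic-scan Gibbs sampler with closed-form full
conditionals:

1. fixed effects and $\beta$ jointly from their Gaussian conditional
   (flat prior);
2. all stacked sire coefficients jointly from a Gaussian conditional with
   prior precision $G_2^{-1} \otimes K^{-1}$;
3. batch, then litter effects (their conditionals factorize over levels);
4. $G_2$ from an inverse-Wishart ($\nu = 4$, $V = 0.1 I$ by default);
5. $\sigma^2_{ba}$, $\sigma^2_{li}$ and each class's $\sigma^2_{et}$ from
   scaled inverse-chi-squares ($\nu = 3$, scale $0.1\,\mathrm{var}(y)$).

The priors are weakly informative and configurable; the paper-scale data
the defaults emulate overwhelm them. Initialization is at the OLS
fixed-effect solution with random effects at zero and variances at
$\mathrm{var}(y)/4$. Blocked updates (one multivariate draw for all
$2S$ sire coefficients) keep mixing fast even though intercept and slope
coefficients of the same sire are strongly correlated. The residual
vector is carried incrementally and refreshed from scratch every 500
iterations to stop floating-point drift; a variance exceeding $10^6
\times \mathrm{var}(y)$ aborts with a diagnostic. A fixed seed makes the
chain bit-reproducible; retained draws number
$\lfloor(\mathrm{iter}-\mathrm{burnin})/\mathrm{thin}\rfloor$ (the
conventional 300,000 / 50,000 / 50 settings retain 5,000).

# Genetic-parameter trajectories

With $\Phi$ the grid basis matrix (rows $(1, s)$, optionally $P_2(s)$),
the sire (co)variance between environments is
$\Gamma = \Phi G_2 \Phi'$ &mdash; oriented grid &times; grid, the only
shape-consistent reading. Heritability at grid point $m$ is the
variance ratio
$$h^2_m = \frac{\Gamma_{mm}}
  {\Gamma_{mm} + \sigma^2_{ba} + \sigma^2_{li} + \sigma^2_{e(t(m))}},$$
where $t(m)$ is the residual class whose covariate interval contains grid
point $m$ &mdash; the class structure is the model's own statement of how
residual variance depends on the environment, so it is the natural choice
of denominator. Note this is the *sire*-variance fraction as reported in
reaction-norm sire analyses of this kind, not the conventional additive
heritability; `h2_point(..., sire_to_additive = TRUE)` applies the
$4\times$ sire-model conversion for readers who want it (default off).
$h^2_m$ and $\Gamma$ are computed per posterior draw and summarized by
the mean and central 95% empirical interval.

Genetic correlations between environments are
$\Gamma_{mm'}/\sqrt{\Gamma_{mm}\Gamma_{m'm'}}$. For an order-1 model
with diagonal $G_2$ evaluated at $s = \pm1$ this collapses to
$(\sigma_0^2 - \sigma_1^2)/(\sigma_0^2 + \sigma_1^2)$, a useful
closed-form check: slope/intercept variance ratios of 0.06838, 1/3 and
0.6611 give extreme-environment correlations 0.872, 0.5 and 0.204.
Correlations below about 0.7 are conventionally read as evidence of
genotype-by-environment interaction.

Reaction norms are $r_m = \alpha + \beta\phi_{1m}$ at the population
level and $r_{mn} = (\alpha + a_{0n}) + (\beta + a_{1n})\phi_{1m}$ per
sire &mdash; the intercept-plus-slope line; a sire with $a_{0n} = a_{1n}
= 0$ coincides with the population line. Genotyped sires are ranked by
posterior-mean $a_0$ (top/bottom 20: `intHi`/`intLo`, overall merit) and
by posterior-mean $a_1$ (`sloHi`/`sloLo`, environmental sensitivity);
ties break by sire identifier so rankings are deterministic.

# The synthetic-data generator

The datasets the package was designed around are commercially owned, so
the generator is a first-class module: it emulates their structure closely
enough that every pipeline stage, and the parameter-recovery properties of
the sampler, can be exercised without external data.

Defaults mirror the study population: 407 sires (279 genotyped), three
farms/stations, 84 nominal harvest batches (farm &times; harvest-date
bins), 22 dam lines, parities 1&ndash;8, single-sire litters with
truncated-Poisson(9) sizes, gender 50/50, cross-fostering
Bernoulli(0.1), harvest at 178 &plusmn; 10.6 days targeting 136 kg (SD
6 kg &mdash; the target-weight system harvests by batch, leaving
intra-batch spread; the SD is the package's choice as no dispersion is
published). The backfat calibration sets mean 18.7 mm and SD 4.11 mm,
decomposed as sire intercept variance 5.4, slope variance
$0.06838 \times 5.4$ (so the extreme-environment correlation is 0.872),
batch 2.0, litter 3.0, residual 6.4 per class &mdash; a flat
sire-variance-ratio heritability of 0.32. Weather is a sinusoidal annual
cycle (mean 11.5 &deg;C, amplitude 13.5 &deg;C, warmest mid-July) with a
diurnal cycle and Gaussian noise, spanning cold (&lt;10&deg;C), mild and
hot (&gt;20&deg;C) regimes as a Midwest series does; humidity sits near
72% with mild seasonality.

Two generator choices deserve emphasis:

* **Exact-moment standardization.** Every random-effect vector (batch,
  litter, per-class residuals) and the harvest age/weight draws are
  centred and rescaled to their exact nominal first and second moments
  after drawing &mdash; the `mvrnorm(empirical = TRUE)` convention.
  Sire coefficient pairs are standardized in the *whitened* domain: the
  white-noise matrix is moment-standardized before Cholesky colouring
  with the pedigree kernel, so the $K$-whitened coefficient covariance
  $U'K^{-1}U/S$ &mdash; the quadratic form the model's
  coefficient-covariance estimator actually targets &mdash; equals the
  nominal $G_2$ exactly while the kernel-induced correlation among sires
  is preserved. Finally the assembled phenotype vector is affinely
  standardized to the exact component-sum variance and target mean,
  because clustered random effects otherwise leave the realized trait
  moments $O(1/\sqrt{S})$ away from their nominal values; variance
  *ratios* (heritability, genetic correlations) are invariant to that
  common rescaling. Generated data therefore carry the target
  parameters themselves, not a Monte-Carlo perturbation of them, and
  calibration/recovery checks test the *estimator* rather than the
  generator's sampling noise.
* **Independent SNPs.** Genotypes are independent markers with MAF
  $\sim U(0.05, 0.5)$ at Hardy-Weinberg proportions, and are not
  generated down the pedigree. That suffices to exercise G and H
  construction mechanically but carries no linkage disequilibrium and no
  pedigree signal, so passing tests say nothing about the *accuracy*
  gain of genomic information on real data &mdash; only about the
  correctness of the matrix algebra and the sampler.

Other simplifications: no selection or culling, spatially identical
weather processes across the three stations (small mean offsets only),
and litters nested in single farms. The grouped fixed effects are small
(tenths of a trait SD), as systematic effects on carcass traits typically
are.

# Problem sizes and numerical choices

Routine tests run at 15&ndash;60 sires with 300&ndash;2,500 records and
chains of 1,500&ndash;3,000 iterations; the correlation-recovery and
heritability-recovery checks run 200 sires &times; 40 offspring (8,000
records) with 6,000&ndash;20,000 iterations, burn-in 2,000&ndash;5,000,
thinning 4&ndash;10 &mdash; sizes chosen so a desk machine
completes a fit in minutes while leaving the posterior-mean heritability
estimate's Monte-Carlo error near 0.03. Paper-scale generation (126,000
records) works but is not a routine test. Other fixed numerical choices:
the covariate grid defaults to 50 equally spaced points over the observed
range; `a_matrix` processes animals parents-first and errors on cycles;
`h_matrix` inverts $A_{22}$ directly (407 sires are dense-tractable &mdash;
no sparse approximations); degenerate designs (single-level factors,
aliased columns) are folded out with messages rather than errors;
effective sample sizes use Geyer's initial positive-sequence truncation.

One identification fact discovered while validating the pipeline is worth
recording: because littermates share a birth date and farm, the
environmental covariate is constant within litters, so the sire *slope*
variance is identified only through between-litter contrasts within sire
families (roughly 4&ndash;5 litters per sire at the test scale). With
realistic litter and residual variances the slope-variance posterior is
therefore wide at 200 sires &mdash; point recovery of an
extreme-environment correlation of 0.5 then carries a Monte-Carlo spread
of roughly &plusmn;0.15. The correlation-recovery check consequently uses
small nuisance variances (batch and litter 0.01, residual 0.2 against a
sire intercept variance of 0.5), which isolates the reaction-norm
machinery it targets; recovery of batch, litter and residual components
under realistic magnitudes is covered separately by the heritability
recovery and full-model recovery checks. At the study's own scale
(126,000 records, ~50 litters per sire) this identification constraint
is far milder.

# Known limitations

Outdoor station weather is a coarse proxy for barn microclimate; the
package inherits that limitation by design. The screening stage follows
the printed fixed-effects model, which omits contemporary-group and
litter terms; the random-regression stage includes batch and litter but
likewise no contemporary group. The sire model estimates only the sire
(quarter-additive) component; maternal and dominance variance are out of
scope, as are multi-trait models, REML estimation, and economic index
construction on the rankings.
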