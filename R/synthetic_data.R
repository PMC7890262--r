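#' Ground-truth parameter set for the synthetic-data generator
#'
#' Collects the structure sizes, trait calibration, fixed effects and
#' variance components used to simulate a data set with the statistical
#' structure the random-regression sire model assumes.  Defaults emulate
#' the study population: 407 Duroc sires (279 genotyped), three farms, 84
#' nominal harvest batches, 22 dam lines, parities 1-8, Poisson(9) litters,
#' harvest at 178 +/- 10.6 days targeting ~136 kg, and backfat-depth
#' calibration (mean 18.7 mm, SD 4.11 mm) with a flat sire-variance-ratio
#' heritability of 0.32 and an extreme-environment genetic correlation of
#' 0.872 (slope/intercept variance ratio 0.06838).
#'
#' @param n_sires,n_genotyped Number of sires and genotyped sires.
#' @param n_offspring Number of phenotyped offspring.
#' @param n_dam_lines,n_parities,n_batches,n_farms Structure sizes.
#' @param litter_mean Mean litter size (Poisson, truncated at 1).
#' @param n_snps Number of simulated independent SNPs.
#' @param trait,trait_mean,trait_sd Trait name and target moments.
#' @param covariate Environmental covariate driving the reaction norms.
#' @param beta Fixed regression on the standardized covariate.
#' @param s2_int,s2_slope,cov_int_slope Sire coefficient (co)variances.
#' @param s2_batch,s2_litter Batch and litter variances.
#' @param s2_e Residual variance, scalar (all classes) or one per class.
#' @param residual_classes Number of covariate-decile residual classes.
#' @param cf_effect,gender_effects,parity_sd,dam_line_sd Fixed-effect values.
#' @param harvest_age_mean,harvest_age_sd,harvest_wt_mean,harvest_wt_sd
#'   Harvest age (days) and target weight (kg) distributions.
#' @param birth_span Character `(from, to)` dates over which litters are
#'   born.
#' @param seed Integer seed for all generator stages.
#' @return List of class `sim_truth`.
#' @export
sim_truth <- function(n_sires = 407L, n_genotyped = 279L,
                      n_offspring = 10000L, n_dam_lines = 22L,
                      n_parities = 8L, n_batches = 84L, n_farms = 3L,
                      litter_mean = 9, n_snps = 1000L,
                      trait = "cBF", trait_mean = 18.7, trait_sd = 4.11,
                      covariate = "rh_92_122", beta = -0.35,
                      s2_int = 5.4, s2_slope = 0.06838 * 5.4,
                      cov_int_slope = 0, s2_batch = 2.0, s2_litter = 3.0,
                      s2_e = 6.4, residual_classes = 10L,
                      cf_effect = -0.2,
                      gender_effects = c(gilt = -0.15, barrow = 0.15),
                      parity_sd = 0.1, dam_line_sd = 0.1,
                      harvest_age_mean = 178, harvest_age_sd = 10.6,
                      harvest_wt_mean = 136, harvest_wt_sd = 6,
                      birth_span = c("2015-09-01", "2018-12-31"),
                      seed = 1L) {
  if (n_genotyped > n_sires) {
    stop("cannot genotype ", n_genotyped, " of ", n_sires, " sires")
  }
  stopifnot(n_sires >= 1L, n_offspring >= 1L, s2_int >= 0, s2_slope >= 0,
            s2_batch >= 0, s2_litter >= 0, all(s2_e >= 0))
  G2 <- matrix(c(s2_int, cov_int_slope, cov_int_slope, s2_slope), 2L, 2L)
  if (min(eigen(G2, only.values = TRUE)$values) < -1e-10) {
    stop("sire coefficient covariance is not positive semi-definite")
  }
  if (length(s2_e) == 1L) s2_e <- rep(s2_e, residual_classes)
  if (length(s2_e) != residual_classes) {
    stop("s2_e must have length 1 or residual_classes")
  }
  structure(as.list(environment()), class = "sim_truth")
}

# center a draw and rescale to exact target (co)variance, so the generated
# data carry the nominal components rather than a Monte-Carlo perturbation
# (the mvrnorm empirical=TRUE convention).  Zero-variance dimensions are
# returned as exact zeros.
scale_to_moments <- function(U, Sigma) {
  U <- as.matrix(U)
  Sigma <- as.matrix(Sigma)
  U <- sweep(U, 2L, colMeans(U))
  live <- diag(Sigma) > 0
  out <- matrix(0, nrow(U), ncol(U))
  if (any(live)) {
    Ul <- U[, live, drop = FALSE]
    C <- crossprod(Ul) / nrow(Ul)
    M <- solve(chol(C)) %*% chol(Sigma[live, live, drop = FALSE])
    out[, live] <- Ul %*% M
  }
  out
}

#' Simulate the population structure
#'
#' Generates a two-generation sire pedigree (grandparents as founders, so
#' sires form half-sib families and the pedigree relationship matrix is
#' non-trivial), SNP genotypes for the genotyped sires (independent markers
#' with MAF ~ Uniform(0.05, 0.5), Hardy-Weinberg dosages), and an offspring
#' table: single-sire litters with Poisson-truncated sizes, dam line,
#' parity, farm, birth date, gender, cross-fostering ~ Bernoulli(0.1),
#' individual harvest age and weight, and harvest batches formed by
#' crossing farm with harvest-date bins (approximately `n_batches` levels).
#'
#' @param truth A [sim_truth()].
#' @return List with `pedigree` (animal/sire/dam), `markers` (dosage matrix
#'   over genotyped sires), `animals` (offspring table), `sires`,
#'   `genotyped`, `farm_station`.
#' @export
simulate_structure <- function(truth) {
  stopifnot(inherits(truth, "sim_truth"))
  set.seed(truth$seed)
  S <- truth$n_sires
  sires <- sprintf("S%04d", seq_len(S))
  n_gs <- max(2L, ceiling(S / 5L))
  gsire <- sprintf("GS%03d", seq_len(n_gs))
  gdam <- sprintf("GD%03d", seq_len(n_gs))
  pedigree <- rbind(
    data.frame(animal = c(gsire, gdam), sire = NA_character_,
               dam = NA_character_, stringsAsFactors = FALSE),
    data.frame(animal = sires, sire = sample(gsire, S, replace = TRUE),
               dam = sample(gdam, S, replace = TRUE),
               stringsAsFactors = FALSE)
  )
  genotyped <- sires[seq_len(truth$n_genotyped)]
  maf <- stats::runif(truth$n_snps, 0.05, 0.5)
  markers <- matrix(
    stats::rbinom(truth$n_genotyped * truth$n_snps, 2L,
                  rep(maf, each = truth$n_genotyped)),
    nrow = truth$n_genotyped,
    dimnames = list(genotyped, sprintf("snp%05d", seq_len(truth$n_snps)))
  )

  # litters until the offspring target is reached
  n_lit_guess <- ceiling(1.3 * truth$n_offspring / truth$litter_mean)
  sizes <- pmax(1L, stats::rpois(n_lit_guess, truth$litter_mean))
  while (sum(sizes) < truth$n_offspring) {
    sizes <- c(sizes, pmax(1L, stats::rpois(n_lit_guess, truth$litter_mean)))
  }
  n_lit <- which(cumsum(sizes) >= truth$n_offspring)[1L]
  sizes <- sizes[seq_len(n_lit)]
  lit_sire <- sample(sires, n_lit, replace = TRUE)
  lit_dam_line <- sample(seq_len(truth$n_dam_lines), n_lit, replace = TRUE)
  lit_parity <- sample(seq_len(truth$n_parities), n_lit, replace = TRUE)
  lit_farm <- sample(seq_len(truth$n_farms), n_lit, replace = TRUE)
  span <- as.Date(truth$birth_span)
  lit_birth <- span[1L] + sample.int(as.integer(span[2L] - span[1L]) + 1L,
                                     n_lit, replace = TRUE) - 1L

  idx <- rep(seq_len(n_lit), sizes)
  n <- length(idx)
  animals <- data.frame(
    animal = sprintf("P%06d", seq_len(n)),
    sire = lit_sire[idx],
    litter = sprintf("L%05d", idx),
    farm = paste0("F", lit_farm[idx]),
    birth_date = lit_birth[idx],
    dam_line = lit_dam_line[idx],
    parity = lit_parity[idx],
    gender = sample(c("gilt", "barrow"), n, replace = TRUE),
    cf = stats::rbinom(n, 1L, 0.1),
    stringsAsFactors = FALSE
  )
  animals <- animals[seq_len(truth$n_offspring), , drop = FALSE]
  n <- nrow(animals)
  animals$harvest_age <- truth$harvest_age_mean +
    scale_to_moments(stats::rnorm(n), truth$harvest_age_sd^2)[, 1L]
  animals$harvest_weight <- truth$harvest_wt_mean +
    scale_to_moments(stats::rnorm(n), truth$harvest_wt_sd^2)[, 1L]
  harvest_date <- animals$birth_date + round(animals$harvest_age)
  n_bins <- max(1L, round(truth$n_batches / truth$n_farms))
  bin <- as.integer(cut(as.numeric(harvest_date), breaks = n_bins,
                        labels = FALSE, include.lowest = TRUE))
  animals$batch <- sprintf("B%s_%02d", animals$farm, bin)

  farm_station <- data.frame(farm = paste0("F", seq_len(truth$n_farms)),
                             station = paste0("ST", seq_len(truth$n_farms)),
                             stringsAsFactors = FALSE)
  list(pedigree = pedigree, markers = markers, animals = animals,
       sires = sires, genotyped = genotyped, farm_station = farm_station)
}

#' Simulate hourly weather with Midwest-like seasonality
#'
#' Sinusoidal annual temperature cycle (coldest mid-January, warmest
#' mid-July) plus a diurnal cycle and Gaussian noise, parameterized so
#' daily means span cold (<10 C), mild (10-20 C) and hot (>20 C) regimes;
#' relative humidity around 72% with mild seasonality, clamped to
#' [20, 100].
#'
#' @param years Number of calendar years, starting at `start`.
#' @param seed Integer seed.
#' @param stations Station identifiers (small temperature offsets apart).
#' @param start First day (default `"2015-01-01"`).
#' @param temp_mean,temp_amp Annual mean and seasonal amplitude (C).
#' @param diurnal_amp Within-day amplitude (C).
#' @param noise_sd_temp,noise_sd_rh Gaussian noise SDs.
#' @return Hourly weather data frame (`station`, `timestamp`, `temp_c`,
#'   `rh`).
#' @export
simulate_weather <- function(years, seed = 1L,
                             stations = c("ST1", "ST2", "ST3"),
                             start = "2015-01-01", temp_mean = 11.5,
                             temp_amp = 13.5, diurnal_amp = 4,
                             noise_sd_temp = 3, noise_sd_rh = 8) {
  stopifnot(years >= 1)
  set.seed(seed)
  t0 <- as.POSIXct(paste(start, "00:00:00"), tz = "UTC")
  hours <- seq(t0, by = "1 hour", length.out = round(years * 365.25 * 24))
  doy <- as.POSIXlt(hours)$yday + 1L
  hod <- as.POSIXlt(hours)$hour
  season <- cos(2 * pi * (doy - 196) / 365.25)       # peak mid-July
  diurnal <- -cos(2 * pi * (hod - 15) / 24)          # peak mid-afternoon
  out <- lapply(seq_along(stations), function(k) {
    off <- 0.5 * (k - (length(stations) + 1) / 2)
    temp <- temp_mean + off + temp_amp * season + diurnal_amp * diurnal +
      stats::rnorm(length(hours), 0, noise_sd_temp)
    rh <- 72 - 3 * season - 2 * diurnal +
      stats::rnorm(length(hours), 0, noise_sd_rh)
    data.frame(station = stations[k], timestamp = hours, temp_c = temp,
               rh = pmin(100, pmax(20, rh)), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Simulate phenotypes under the reaction-norm sire model
#'
#' Assembles trait records exactly per the fitted model: intercept,
#' cross-fostering, parity, gender and dam-line effects, the fixed
#' regression on the standardized covariate, sire intercept/slope pairs
#' drawn from `N(0, G2 (x) K)` with `K` the pedigree sire kernel, iid batch
#' and litter effects, and residuals with the variance of the record's
#' covariate-decile class.  All random-effect vectors are centered and
#' rescaled to their exact nominal moments (see the package vignette), so
#' generated data carry the target variance components; the intercept is
#' calibrated so the population mean equals `truth$trait_mean`.
#'
#' @param structure A [simulate_structure()] result.
#' @param heatload Heat-load covariates for the structure's animals.
#' @param truth The [sim_truth()] used for the structure.
#' @return Phenotype data frame: `animal`, `sire`, `litter`, `batch`, `cf`,
#'   `parity`, `gender`, `dam_line`, `harvest_age`, `harvest_weight` and
#'   the trait column.  Attribute `truth_effects` records the realized
#'   fixed-effect values and standardization range.
#' @export
simulate_phenotypes <- function(structure, heatload, truth) {
  stopifnot(inherits(truth, "sim_truth"))
  an <- structure$animals
  m <- match(an$animal, heatload$animal)
  if (anyNA(m)) {
    stop(sum(is.na(m)), " animal(s) lack heat-load covariates")
  }
  cov <- heatload[[truth$covariate]][m]
  if (is.null(cov)) stop("covariate ", truth$covariate,
                         " absent from heat-load table")
  set.seed(truth$seed + 1L)
  rng <- base::range(cov)
  s <- 2 * (cov - rng[1L]) / (rng[2L] - rng[1L]) - 1

  # fixed effects (centered level values, scaled trait units)
  sc <- truth$trait_sd / 4.11
  par_eff <- scale_to_moments(stats::rnorm(truth$n_parities),
                              (sc * truth$parity_sd)^2)[, 1L]
  dl_eff <- scale_to_moments(stats::rnorm(truth$n_dam_lines),
                             (sc * truth$dam_line_sd)^2)[, 1L]
  gen_eff <- truth$gender_effects * sc
  fixed_part <- truth$cf_effect * sc * an$cf +
    par_eff[an$parity] + dl_eff[an$dam_line] +
    gen_eff[match(an$gender, names(gen_eff))] +
    truth$beta * sc * s
  alpha <- truth$trait_mean - mean(fixed_part)

  # sire coefficients ~ N(0, G2 (x) K), K = pedigree sire kernel.  The
  # white-noise matrix is standardized before the Cholesky colouring, so
  # the K-whitened coefficient covariance U' K^-1 U / S -- the quadratic
  # form the model's coefficient-covariance estimator targets -- equals G2
  # exactly.
  G2 <- matrix(c(truth$s2_int, truth$cov_int_slope,
                 truth$cov_int_slope, truth$s2_slope), 2L, 2L)
  A <- a_matrix(structure$pedigree)
  K <- sire_block(A, structure$sires)
  S <- length(structure$sires)
  LK <- chol(K + diag(1e-8, S))
  Zw <- scale_to_moments(matrix(stats::rnorm(2L * S), S, 2L), diag(2L))
  eg <- eigen(G2, symmetric = TRUE)
  G2half <- eg$vectors %*% (sqrt(pmax(eg$values, 0)) * t(eg$vectors))
  U <- crossprod(LK, Zw) %*% G2half
  rownames(U) <- structure$sires
  si <- match(an$sire, structure$sires)

  batch_f <- factor(an$batch)
  litter_f <- factor(an$litter)
  be <- scale_to_moments(stats::rnorm(nlevels(batch_f)),
                         truth$s2_batch)[, 1L]
  le <- scale_to_moments(stats::rnorm(nlevels(litter_f)),
                         truth$s2_litter)[, 1L]

  rcl <- assign_residual_classes(cov, truth$residual_classes)
  e <- numeric(nrow(an))
  for (t in seq_len(truth$residual_classes)) {
    it <- which(rcl == t)
    if (length(it) > 1L) {
      e[it] <- scale_to_moments(stats::rnorm(length(it)),
                                truth$s2_e[t])[, 1L]
    }
  }

  y <- alpha + fixed_part + U[si, 1L] + U[si, 2L] * s +
    be[as.integer(batch_f)] + le[as.integer(litter_f)] + e

  # final moment calibration: clustered random effects leave the realized
  # phenotype mean and variance O(1/sqrt(n_sires)) away from their nominal
  # values, so the assembled vector is affinely standardized to the exact
  # component-sum variance and target mean.  Ratios of variance components
  # (heritability, genetic correlations) are invariant to this common
  # rescaling; individual components move by well under a percent at the
  # default sizes.
  pvar <- function(x) mean((x - mean(x))^2)
  n_t <- tabulate(rcl, truth$residual_classes)
  target_var <- pvar(fixed_part) + truth$s2_int +
    2 * truth$cov_int_slope * mean(s) + truth$s2_slope * mean(s^2) +
    truth$s2_batch + truth$s2_litter +
    sum(n_t * truth$s2_e) / length(y)
  if (pvar(y) > 1e-12 && target_var > 0) {
    y <- truth$trait_mean + (y - mean(y)) * sqrt(target_var / pvar(y))
  }

  phen <- data.frame(
    animal = an$animal, sire = an$sire, litter = an$litter,
    batch = an$batch, cf = an$cf, parity = an$parity, gender = an$gender,
    dam_line = an$dam_line, harvest_age = an$harvest_age,
    harvest_weight = an$harvest_weight, stringsAsFactors = FALSE
  )
  phen[[truth$trait]] <- y
  attr(phen, "truth_effects") <- list(
    alpha = alpha, beta = truth$beta * sc, parity = par_eff,
    dam_line = dl_eff, gender = gen_eff, cf = truth$cf_effect * sc,
    range = rng, sire_coef = U
  )
  phen
}

#' Simulate a complete analysis-ready data set
#'
#' Convenience wrapper running [simulate_weather()],
#' [simulate_structure()], [daily_aggregate()], [lifetime_covariates()]
#' and [simulate_phenotypes()] with consistent seeds derived from
#' `truth$seed`.
#'
#' @param truth A [sim_truth()].
#' @return List `weather`, `daily`, `structure`, `heatload`, `phen`,
#'   `truth`.
#' @export
simulate_dataset <- function(truth = sim_truth()) {
  span <- as.Date(truth$birth_span)
  years <- ceiling(as.numeric(span[2L] + 160L -
                              as.Date("2015-01-01")) / 365.25)
  weather <- simulate_weather(years, seed = truth$seed + 2L)
  structure <- simulate_structure(truth)
  daily <- daily_aggregate(weather)
  heatload <- lifetime_covariates(
    structure$animals[c("animal", "birth_date", "farm")],
    structure$farm_station, daily)
  phen <- simulate_phenotypes(structure, heatload, truth)
  list(weather = weather, daily = daily, structure = structure,
       heatload = heatload, phen = phen, truth = truth)
}
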