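#' Legendre polynomial basis on a standardized covariate
#'
#' Standardizes `x` to `s = 2 (x - min) / (max - min) - 1` on `[-1, 1]` and
#' returns the Legendre columns `P0(s) = 1`, `P1(s) = s` and, for
#' `order = 2`, `P2(s) = (3 s^2 - 1) / 2`.
#'
#' @param x Numeric covariate vector.
#' @param order Polynomial order, 1 or 2.
#' @param range Length-2 numeric `(min, max)` standardization range; defaults
#'   to `range(x)`.  Persist and reuse this so that later model stages map
#'   the covariate identically.
#' @return Matrix with `order + 1` columns named `p0`, `p1` (and `p2`);
#'   attribute `range` records the standardization range.
#' @export
legendre_basis <- function(x, order = 1L, range = base::range(x)) {
  if (!order %in% c(1L, 2L)) stop("order must be 1 or 2")
  if (length(range) != 2L || !is.finite(range[1L]) || !is.finite(range[2L]) ||
      range[2L] <= range[1L]) {
    stop("invalid standardization range: max must exceed min ",
         "(constant covariate?)")
  }
  s <- 2 * (x - range[1L]) / (range[2L] - range[1L]) - 1
  b <- cbind(p0 = rep(1, length(s)), p1 = s)
  if (order == 2L) b <- cbind(b, p2 = (3 * s^2 - 1) / 2)
  attr(b, "range") <- as.numeric(range)
  b
}

#' Fixed-effects screening fit for one trait / covariate pair
#'
#' Ordinary least-squares fit of a trait on an intercept, the systematic
#' factors (cross-fostering, parity, gender, dam line), and the Legendre
#' polynomial of an environmental covariate.  Reports the coefficient of
#' determination and Gaussian BIC (`-2 loglik + k log n`, `k` = mean
#' parameters + 1 for the residual variance).
#'
#' @param y Numeric trait vector.
#' @param factors Data frame of factor columns (coerced with `factor()`).
#' @param covariate Numeric environmental covariate vector.
#' @param order Legendre order for the covariate term (1 or 2).
#' @param range Standardization range passed to [legendre_basis()].
#' @return List with `r2`, `bic`, `n`, `k`, `fit` (the `lm` object) and
#'   `range`.
#' @export
fit_fixed_model <- function(y, factors, covariate, order = 1L,
                            range = base::range(covariate)) {
  keep <- stats::complete.cases(y, factors, covariate)
  y <- y[keep]
  covariate <- covariate[keep]
  factors <- factors[keep, , drop = FALSE]
  basis <- legendre_basis(covariate, order = order, range = range)
  dat <- data.frame(y = y, lapply(factors, factor),
                    basis[, -1L, drop = FALSE], check.names = TRUE)
  fit <- stats::lm(y ~ ., data = dat)
  if (anyNA(stats::coef(fit))) {
    warning("rank-deficient screening design; aliased column(s) dropped: ",
            paste(names(stats::coef(fit))[is.na(stats::coef(fit))],
                  collapse = ", "))
  }
  n <- length(y)
  k <- sum(!is.na(stats::coef(fit))) + 1L  # + residual variance
  ll <- as.numeric(stats::logLik(fit))
  list(r2 = summary(fit)$r.squared, bic = -2 * ll + k * log(n),
       n = n, k = k, fit = fit, range = attr(basis, "range"))
}

#' Screen all trait-by-covariate combinations
#'
#' Fits the fixed-effects screening model for every trait crossed with every
#' environmental covariate column of the heat-load table, and flags, per
#' trait, the winning covariate by maximal R-squared and by minimal
#' (order-1) BIC separately -- the two criteria may disagree.
#'
#' @param phen Phenotype data frame with column `animal`, the trait columns,
#'   and the factor columns `cf`, `parity`, `gender`, `dam_line`.
#' @param heatload Heat-load covariate table from [lifetime_covariates()].
#' @param traits Character vector of trait column names in `phen`.
#' @param covariates Covariate column names (default: all non-`animal`
#'   columns of `heatload`).
#' @return Data frame with one row per combination: `trait`, `variable`,
#'   `window`, `covariate`, `r2`, `bic_order1`, `bic_order2`, `converged`,
#'   `best_r2`, `best_bic`.  Attribute `ranges` is a named list of the
#'   per-covariate standardization ranges for reuse in the random-regression
#'   stage.
#' @export
screen_all <- function(phen, heatload, traits,
                       covariates = setdiff(names(heatload), "animal")) {
  dat <- merge(phen, heatload, by = "animal")
  if (nrow(dat) == 0L) stop("phenotype/heat-load join produced zero rows")
  fac_cols <- c("cf", "parity", "gender", "dam_line")
  miss <- setdiff(c(fac_cols, traits, covariates), names(dat))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))

  ranges <- lapply(covariates, function(cv) base::range(dat[[cv]]))
  names(ranges) <- covariates
  rows <- vector("list", length(traits) * length(covariates))
  i <- 0L
  for (tr in traits) {
    for (cv in covariates) {
      i <- i + 1L
      f1 <- fit_fixed_model(dat[[tr]], dat[fac_cols], dat[[cv]],
                            order = 1L, range = ranges[[cv]])
      f2 <- fit_fixed_model(dat[[tr]], dat[fac_cols], dat[[cv]],
                            order = 2L, range = ranges[[cv]])
      parts <- strsplit(cv, "_", fixed = TRUE)[[1L]]
      rows[[i]] <- data.frame(
        trait = tr,
        variable = c(thi = "THI", temp = "Temp", rh = "RH")[parts[1L]],
        window = paste(parts[-1L], collapse = "-"),
        covariate = cv, r2 = f1$r2, bic_order1 = f1$bic, bic_order2 = f2$bic,
        converged = TRUE, row.names = NULL
      )
    }
  }
  out <- do.call(rbind, rows)
  out$best_r2 <- out$best_bic <- FALSE
  for (tr in traits) {
    ii <- which(out$trait == tr)
    out$best_r2[ii[which.max(out$r2[ii])]] <- TRUE
    out$best_bic[ii[which.min(out$bic_order1[ii])]] <- TRUE
  }
  attr(out, "ranges") <- ranges
  out
}
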