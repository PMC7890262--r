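#' Covariate evaluation grid
#'
#' Equally spaced grid over the covariate range, with the standardized
#' values `s` in `[-1, 1]` and the Legendre basis matrix whose rows are
#' `(1, s[, P2(s)])`.
#'
#' @param range Length-2 `(min, max)` covariate range.
#' @param n Number of grid points (default 50).
#' @param order Legendre order (1 or 2).
#' @return List with `values`, `s`, `Phi` (n x (order+1)); class
#'   `covariate_grid`.
#' @export
covariate_grid <- function(range, n = 50L, order = 1L) {
  stopifnot(n >= 2L)
  values <- seq(range[1L], range[2L], length.out = n)
  Phi <- legendre_basis(values, order = order, range = range)
  structure(list(values = values, s = Phi[, "p1"],
                 Phi = unclass(Phi)[, , drop = FALSE]),
            class = "covariate_grid")
}

#' Additive genetic (co)variance surface over the covariate grid
#'
#' `Gamma = Phi G2 Phi'`, the sire (co)variance between every pair of
#' environment values, from the coefficient covariance `G2` of the
#' random-regression model.
#'
#' @param G2 Symmetric positive semi-definite coefficient covariance
#'   ((order+1) square).
#' @param grid A [covariate_grid()] (its basis order must match `G2`).
#' @return Symmetric grid x grid matrix.
#' @export
gamma_surface <- function(G2, grid) {
  G2 <- as.matrix(G2)
  if (!isSymmetric(G2, tol = 1e-8)) stop("G2 must be symmetric")
  if (min(eigen(G2, symmetric = TRUE, only.values = TRUE)$values) < -1e-8) {
    stop("G2 must be positive semi-definite")
  }
  Phi <- grid$Phi
  if (ncol(Phi) != ncol(G2)) {
    stop("grid basis order does not match the coefficient covariance")
  }
  Phi %*% G2 %*% t(Phi)
}

#' Genetic correlations between environment values
#'
#' @param Gamma Genetic (co)variance surface from [gamma_surface()].
#' @return Correlation matrix with unit diagonal.
#' @export
genetic_correlation_surface <- function(Gamma) {
  d <- diag(Gamma)
  if (any(d <= 0)) stop("Gamma has non-positive diagonal entries; ",
                        "correlations undefined")
  stats::cov2cor(Gamma)
}

#' Heritability at given variance components
#'
#' The sire-variance fraction of the total:
#' `h2 = Gamma_mm / (Gamma_mm + s2_batch + s2_litter + s2_e)` -- the ratio
#' as reported by the reaction-norm analysis, with no sire-to-additive
#' conversion.  Set `sire_to_additive = TRUE` for the conventional sire-model
#' conversion (4 x sire variance in the numerator, added to the denominator
#' remainder).
#'
#' @param gamma_mm Sire variance(s) at the environment value(s).
#' @param s2_batch,s2_litter Batch and litter variance components.
#' @param s2_e Residual variance(s) applying at the environment value(s).
#' @param sire_to_additive Apply the 4x sire-model conversion (default
#'   `FALSE`, matching the as-reported ratio).
#' @return Numeric vector of heritabilities.
#' @export
h2_point <- function(gamma_mm, s2_batch, s2_litter, s2_e,
                     sire_to_additive = FALSE) {
  if (any(c(gamma_mm, s2_batch, s2_litter, s2_e) < 0)) {
    stop("variance components must be non-negative")
  }
  tot <- gamma_mm + s2_batch + s2_litter + s2_e
  if (any(tot == 0)) stop("zero total variance")
  num <- if (sire_to_additive) 4 * gamma_mm else gamma_mm
  den <- if (sire_to_additive) tot + 3 * gamma_mm else tot
  num / den
}

# residual class of each grid value, using the fit's decile cut points
grid_classes <- function(fit, grid) {
  if (length(fit$cutpoints) == 0L) return(rep(1L, length(grid$values)))
  findInterval(grid$values, fit$cutpoints, left.open = TRUE) + 1L
}

#' Heritability trajectory with empirical intervals
#'
#' For each retained posterior draw, forms `Gamma = Phi G2 Phi'` on the
#' grid and the heritability `Gamma_mm / (Gamma_mm + s2_batch + s2_litter +
#' s2_e(class(m)))`, where the residual variance is that of the covariate
#' decile class containing grid point `m`; then summarizes across draws.
#'
#' @param fit An [gibbs_fit()] result.
#' @param grid A [covariate_grid()] over the fit's covariate range (default:
#'   50 points).
#' @param sire_to_additive See [h2_point()].
#' @return Data frame per grid point: `value`, `s`, `class`, `gamma_mean`,
#'   `h2_mean`, `h2_lo`, `h2_hi` (95% empirical interval).
#' @export
heritability_trajectory <- function(fit, grid = NULL,
                                    sire_to_additive = FALSE) {
  stopifnot(inherits(fit, "rrm_fit"))
  if (is.null(grid)) grid <- covariate_grid(fit$range, order = fit$order)
  cls <- grid_classes(fit, grid)
  q <- fit$q
  nd <- nrow(fit$G)
  ng <- length(grid$values)
  h2 <- matrix(NA_real_, nd, ng)
  gm <- matrix(NA_real_, nd, ng)
  iu <- which(upper.tri(diag(q), diag = TRUE))
  for (d in seq_len(nd)) {
    G2 <- matrix(0, q, q)
    G2[iu] <- fit$G[d, ]
    G2[lower.tri(G2)] <- t(G2)[lower.tri(G2)]
    gdiag <- rowSums((grid$Phi %*% G2) * grid$Phi)
    s2e <- fit$sigma2[d, paste0("e_", cls)]
    gm[d, ] <- gdiag
    h2[d, ] <- h2_point(gdiag, fit$sigma2[d, "batch"],
                        fit$sigma2[d, "litter"], s2e,
                        sire_to_additive = sire_to_additive)
  }
  data.frame(
    value = grid$values, s = grid$s, class = cls,
    gamma_mean = colMeans(gm),
    h2_mean = colMeans(h2),
    h2_lo = apply(h2, 2L, stats::quantile, 0.025, names = FALSE),
    h2_hi = apply(h2, 2L, stats::quantile, 0.975, names = FALSE)
  )
}

#' Posterior-mean genetic correlation surface of a fit
#'
#' @param fit An [gibbs_fit()] result.
#' @param grid Optional [covariate_grid()].
#' @return Grid x grid correlation matrix of the posterior-mean `Gamma`.
#' @export
correlation_surface <- function(fit, grid = NULL) {
  stopifnot(inherits(fit, "rrm_fit"))
  if (is.null(grid)) grid <- covariate_grid(fit$range, order = fit$order)
  q <- fit$q
  iu <- which(upper.tri(diag(q), diag = TRUE))
  G2 <- matrix(0, q, q)
  G2[iu] <- colMeans(fit$G)
  G2[lower.tri(G2)] <- t(G2)[lower.tri(G2)]
  genetic_correlation_surface(gamma_surface(G2, grid))
}

#' Population and sire reaction norms
#'
#' Population line `r_m = alpha + beta phi_1m`; per-sire lines
#' `r_mn = (alpha + a0_n) + (beta + a1_n) phi_1m`, evaluated on the grid.
#'
#' @param alpha,beta Population intercept and covariate regression.
#' @param solutions Data frame `sire`, `a0`, `a1` (e.g. [sire_solutions()]).
#' @param grid A [covariate_grid()].
#' @param sires Which sires to evaluate (default all in `solutions`).
#' @return List with `population` (data frame `value`, `s`, `r`) and
#'   `sires` (data frame `sire`, `value`, `s`, `r`).
#' @export
reaction_norms <- function(alpha, beta, solutions, grid,
                           sires = solutions$sire) {
  miss <- setdiff(as.character(sires), as.character(solutions$sire))
  if (length(miss)) stop("no solutions for sire(s): ",
                         paste(miss, collapse = ", "))
  s <- grid$s
  pop <- data.frame(value = grid$values, s = s, r = alpha + beta * s)
  sol <- solutions[match(as.character(sires),
                         as.character(solutions$sire)), , drop = FALSE]
  per <- do.call(rbind, lapply(seq_len(nrow(sol)), function(i) {
    data.frame(sire = sol$sire[i], value = grid$values, s = s,
               r = (alpha + sol$a0[i]) + (beta + sol$a1[i]) * s)
  }))
  list(population = pop, sires = per)
}

#' Rank genotyped sires by reaction-norm intercept and slope
#'
#' The top/bottom `n` genotyped sires by posterior-mean intercept `a0`
#' form the `intHi`/`intLo` groups (overall merit); the top/bottom `n` by
#' slope `a1` form `sloHi`/`sloLo` (environmental sensitivity).  Ties are
#' broken by sire identifier order, so rankings are deterministic.
#'
#' @param solutions Data frame `sire`, `a0`, `a1` (e.g. [sire_solutions()]).
#' @param genotyped Character vector of genotyped sire ids; only these are
#'   eligible for ranking.
#' @param n Group size (default 20).
#' @return Data frame `group`, `rank`, `sire`, `a0`, `a1`.
#' @export
rank_sires <- function(solutions, genotyped, n = 20L) {
  sol <- solutions[as.character(solutions$sire) %in% as.character(genotyped),
                   , drop = FALSE]
  if (nrow(sol) < 2L * n) {
    stop("need at least ", 2L * n, " genotyped sires with solutions; have ",
         nrow(sol))
  }
  sol <- sol[order(as.character(sol$sire)), , drop = FALSE]  # stable ties
  pick <- function(values, decreasing) {
    ord <- order(values, decreasing = decreasing)
    ord[seq_len(n)]
  }
  groups <- list(
    intHi = pick(sol$a0, TRUE), intLo = pick(sol$a0, FALSE),
    sloHi = pick(sol$a1, TRUE), sloLo = pick(sol$a1, FALSE)
  )
  do.call(rbind, lapply(names(groups), function(g) {
    i <- groups[[g]]
    data.frame(group = g, rank = seq_len(n), sire = sol$sire[i],
               a0 = sol$a0[i], a1 = sol$a1[i], row.names = NULL)
  }))
}
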