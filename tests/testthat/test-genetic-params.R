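two_point_grid <- function(order = 1L) covariate_grid(c(-1, 1), n = 2L,
                                                      order = order)

test_that("gamma surface reproduces closed-form extreme correlations", {
  g <- two_point_grid()
  # no slope variance: flat surface, correlation 1 everywhere
  G0 <- diag(c(0.7, 0))
  expect_equal(gamma_surface(G0, g),
               matrix(0.7, 2, 2), ignore_attr = TRUE)
  # diagonal coefficient covariance at s = +/-1:
  # corr = (s0 - s1) / (s0 + s1)
  for (s1 in c(1 / 3, 0.06838, 0.6611)) {
    G2 <- diag(c(1, s1))
    C <- genetic_correlation_surface(gamma_surface(G2, g))
    expect_equal(C[1, 2], (1 - s1) / (1 + s1), tolerance = 1e-12)
    expect_equal(diag(C), c(1, 1), ignore_attr = TRUE)
  }
})

test_that("gamma is quadratic in s with minimum at -cov/slope-variance", {
  G2 <- matrix(c(1, -0.3, -0.3, 0.5), 2, 2)
  grid <- covariate_grid(c(0, 10), n = 201L)
  d <- diag(gamma_surface(G2, grid))
  # second differences constant (quadratic) and argmin at s = 0.3/0.5
  expect_equal(diff(d, differences = 2),
               rep(diff(d, differences = 2)[1], 199L), tolerance = 1e-9)
  expect_equal(grid$s[which.min(d)], -(-0.3) / 0.5, tolerance = 0.011)
})

test_that("gamma surface validates its inputs", {
  g <- two_point_grid()
  expect_error(gamma_surface(matrix(c(1, 0.2, 0.3, 1), 2), g), "symmetric")
  expect_error(gamma_surface(matrix(c(1, 2, 2, 1), 2), g),
               "semi-definite")
  expect_error(gamma_surface(diag(3), g), "order")
})

test_that("correlation surface equals brute-force elementwise computation", {
  set.seed(17)
  L <- matrix(rnorm(4), 2)
  G2 <- crossprod(L) + diag(0.1, 2)
  grid <- covariate_grid(c(60, 80), n = 7L)
  Gam <- gamma_surface(G2, grid)
  C <- genetic_correlation_surface(Gam)
  for (i in 1:7) for (j in 1:7) {
    expect_equal(C[i, j], Gam[i, j] / sqrt(Gam[i, i] * Gam[j, j]))
  }
  expect_error(genetic_correlation_surface(matrix(c(0, 0, 0, 1), 2)),
               "diagonal")
})

test_that("pointwise heritability follows the variance-ratio formula", {
  expect_equal(h2_point(0.16, 0.09, 0.10, 0.15), 0.32)
  expect_equal(h2_point(1, 0, 0, 0), 1)
  expect_equal(h2_point(0, 0.1, 0.1, 0.1), 0)
  # monotone increasing in the sire variance, other components fixed
  gs <- seq(0, 2, by = 0.05)
  expect_true(all(diff(h2_point(gs, 0.2, 0.2, 0.4)) > 0))
  # optional conventional sire-to-additive conversion
  expect_equal(h2_point(0.1, 0.2, 0.3, 0.4, sire_to_additive = TRUE),
               0.4 / 1.3)
  expect_error(h2_point(-0.1, 0, 0, 0.5), "non-negative")
  expect_error(h2_point(0, 0, 0, 0), "zero total")
})

# a deterministic fit-shaped object for trajectory tests
fake_fit <- function(draws_G, sigma2, range = c(0, 1), cutpoints = numeric()) {
  structure(list(
    G = draws_G, sigma2 = sigma2, range = range, cutpoints = cutpoints,
    order = 1L, q = 2L, sire_ids = character(), fixed = NULL
  ), class = "rrm_fit")
}

test_that("heritability trajectory summarizes per-draw ratios with intervals", {
  # two draws with known arithmetic
  G <- rbind(c(0.16, 0, 0), c(0.32, 0, 0))
  colnames(G) <- c("g00", "g01", "g11")
  s2 <- rbind(c(0.09, 0.10, 0.15, 0.15), c(0.09, 0.10, 0.15, 0.15))
  colnames(s2) <- c("batch", "litter", "e_1", "e_2")
  fit <- fake_fit(G, s2, cutpoints = 0.5)
  tr <- heritability_trajectory(fit, covariate_grid(c(0, 1), n = 3L))
  h1 <- 0.16 / 0.50; h2 <- 0.32 / 0.66
  expect_equal(tr$h2_mean, rep(mean(c(h1, h2)), 3L))
  expect_equal(tr$class, c(1L, 1L, 2L))
  expect_true(all(tr$h2_lo <= tr$h2_mean & tr$h2_mean <= tr$h2_hi))
})

test_that("reaction norms evaluate population and sire lines", {
  sol <- data.frame(sire = c("s1", "s2", "s3"),
                    a0 = c(0, 2, 1), a1 = c(0, -0.5, 0))
  grid <- covariate_grid(c(0, 10), n = 3L)  # s = -1, 0, 1
  rn <- reaction_norms(alpha = 10, beta = 1, sol, grid)
  expect_equal(rn$population$r, c(9, 10, 11))
  # a0 = a1 = 0: identical to the population line
  expect_equal(rn$sires$r[rn$sires$sire == "s1"], c(9, 10, 11))
  # a1 = 0: parallel, offset by a0
  expect_equal(rn$sires$r[rn$sires$sire == "s3"], c(10, 11, 12))
  # direct evaluation at s = 1: (10 + 2) + (1 - 0.5) * 1
  expect_equal(rn$sires$r[rn$sires$sire == "s2"][3], 12.5)
  expect_error(reaction_norms(10, 1, sol, grid, sires = "s9"), "s9")
})

test_that("sire ranking forms four deterministic groups of n", {
  set.seed(18)
  sol <- data.frame(sire = sprintf("s%02d", 1:30),
                    a0 = rnorm(30), a1 = rnorm(30))
  rk <- rank_sires(sol, genotyped = sol$sire, n = 5L)
  expect_equal(unname(table(rk$group)[c("intHi", "intLo", "sloHi", "sloLo")]),
               rep(5L, 4L), ignore_attr = TRUE)
  expect_equal(rk$a0[rk$group == "intHi"],
               sort(sol$a0, decreasing = TRUE)[1:5])
  # flipping the intercept sign swaps intHi and intLo membership
  sol2 <- sol; sol2$a0 <- -sol2$a0
  rk2 <- rank_sires(sol2, sol$sire, n = 5L)
  expect_setequal(rk2$sire[rk2$group == "intLo"],
                  rk$sire[rk$group == "intHi"])
  # only genotyped sires are eligible
  rk3 <- rank_sires(sol, genotyped = sol$sire[1:12], n = 5L)
  expect_true(all(rk3$sire %in% sol$sire[1:12]))
  expect_error(rank_sires(sol, sol$sire[1:8], n = 5L), "8")
})

test_that("ties in ranking break by sire identifier order", {
  sol <- data.frame(sire = c("s05", "s01", "s03", "s02", "s04"),
                    a0 = c(1, 1, 1, 0, 0), a1 = 1:5)
  rk <- rank_sires(sol, sol$sire, n = 2L)
  expect_equal(rk$sire[rk$group == "intHi"], c("s01", "s03"))
  rk_again <- rank_sires(sol[c(3, 1, 5, 2, 4), ], sol$sire, n = 2L)
  expect_identical(rk$sire, rk_again$sire)
})

test_that("end-to-end: known extreme-environment correlations are recovered", {
  # simulate with coefficient covariances implying rho in {0.2, 0.5, 0.87}
  # at s = +/-1 and check the fitted pipeline's estimate within +/-0.1;
  # nuisance components are kept small so the slope-variance estimator's
  # Monte-Carlo error stays well inside the band at the 200-sire scale
  s0 <- 0.5
  for (case in list(list(rho = 0.87, seed = 31L),
                    list(rho = 0.5, seed = 32L),
                    list(rho = 0.2, seed = 33L))) {
    s1 <- s0 * (1 - case$rho) / (1 + case$rho)
    tr <- small_truth(n_sires = 200L, n_genotyped = 150L,
                      n_offspring = 8000L, n_snps = 200L, s2_int = s0,
                      s2_slope = s1, cov_int_slope = 0, s2_batch = 0.01,
                      s2_litter = 0.01, s2_e = 0.2, trait_mean = 12,
                      seed = case$seed)
    sim <- simulate_dataset(tr)
    sp <- rrm_spec("cBF", "rh_92_122", n_iter = 6000L, burn_in = 2000L,
                   thin = 4L, seed = case$seed)
    fr <- build_frame(sim$phen, sim$heatload, sp)
    A <- a_matrix(sim$structure$pedigree)
    fit <- gibbs_fit(fr, sire_block(A, fr$sire_ids), sp)
    C <- correlation_surface(fit, covariate_grid(fr$range, n = 2L))
    expect_lt(abs(C[1, 2] - case$rho), 0.1,
              label = paste("extreme-correlation error, truth", case$rho))
  }
})
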