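test_that("retained-draw bookkeeping holds for arbitrary chain settings", {
  cases <- list(c(300000L, 50000L, 50L), c(20000L, 5000L, 10L),
                c(101L, 7L, 13L), c(10L, 9L, 1L))
  for (cs in cases) {
    sp <- rrm_spec("y", "x", n_iter = cs[1], burn_in = cs[2], thin = cs[3])
    expect_equal(n_retained(sp), (cs[1] - cs[2]) %/% cs[3])
  }
  expect_error(rrm_spec("y", "x", n_iter = 100L, burn_in = 100L),
               "burn_in")
})

test_that("residual classes split records at covariate quantiles", {
  x <- seq(0.5, 99.5, by = 1)  # 100 values, 10 classes of 10
  cl <- assign_residual_classes(x, 10L)
  expect_equal(unname(table(cl)), rep(10L, 10L), ignore_attr = TRUE)
  expect_true(all(diff(cl[order(x)]) >= 0))

  expect_equal(assign_residual_classes(rnorm(5), 1L), rep(1L, 5L),
               ignore_attr = TRUE)
  expect_error(assign_residual_classes(rep(1, 10), 4L), "constant")

  # skewed draws: sizes stay near-equal (slack = tied boundary values)
  set.seed(10)
  xs <- rexp(1000L)
  szs <- table(assign_residual_classes(xs, 10L))
  expect_lte(max(szs) - min(szs), 1L + sum(duplicated(xs)))
  # boundary values fall in the lower class
  q <- quantile(xs, seq(0.1, 0.9, by = 0.1), names = FALSE)
  clb <- assign_residual_classes(c(xs, q[3]), 10L)
  expect_equal(clb[length(clb)], 3L)
})

test_that("build_frame assembles hand-checkable incidence structures", {
  phen <- data.frame(
    animal = paste0("p", 1:5), sire = c("s1", "s1", "s2", "s2", "s2"),
    litter = c("l1", "l1", "l2", "l2", "l3"),
    batch = c("b1", "b1", "b1", "b2", "b2"),
    cf = c(0, 1, 0, 0, 1), parity = c(1, 1, 2, 2, 1),
    gender = c("gilt", "barrow", "gilt", "barrow", "gilt"),
    dam_line = c(1, 2, 1, 2, 1),
    y = c(10, 11, 12, 13, 14), x = c(60, 65, 70, 75, 80)
  )
  sp <- rrm_spec("y", "x", n_iter = 10L, burn_in = 5L, thin = 1L,
                 residual_classes = 2L)
  fr <- build_frame(phen, phen[c("animal", "x")], sp)
  expect_equal(unname(fr$X[, "(Intercept)"]), rep(1, 5))
  expect_equal(unname(fr$X[, "cf1"]), c(0, 1, 0, 0, 1))
  expect_equal(unname(fr$X[, "gendergilt"]),
               as.numeric(phen$gender == "gilt"))
  expect_equal(unname(fr$X[, "p1"]), c(-1, -0.5, 0, 0.5, 1))
  expect_equal(fr$B[, 1], rep(1, 5), ignore_attr = TRUE)
  expect_equal(fr$sire, c(1L, 1L, 2L, 2L, 2L))
  expect_equal(fr$litter, c(1L, 1L, 2L, 2L, 3L))
  expect_equal(fr$batch, c(1L, 1L, 1L, 2L, 2L))
  # covariate at the range midpoint has p1 = 0
  expect_equal(fr$X[phen$x == 70, "p1"], 0, ignore_attr = TRUE)
})

test_that("build_frame folds degenerate factors and drops incomplete records", {
  phen <- data.frame(
    animal = paste0("p", 1:6), sire = rep(c("s1", "s2"), 3),
    litter = rep(c("l1", "l2"), each = 3), batch = "b1",
    cf = 0, parity = 1, gender = "gilt", dam_line = rep(1:2, 3),
    y = c(1:5, NA), x = c(10, 12, 14, 16, 18, 20)
  )
  sp <- rrm_spec("y", "x", n_iter = 10L, burn_in = 2L, thin = 1L,
                 residual_classes = 2L)
  expect_message(fr <- build_frame(phen, phen[c("animal", "x")], sp),
                 "single level")
  expect_equal(length(fr$y), 5L)
  expect_equal(fr$n_dropped, 1L)
  expect_false(any(grepl("gender|cf|parity", colnames(fr$X))))
})

# compact generator for fitter tests: explicit one-way-plus-slope data
oneway_data <- function(S, k, mu, s2_sire, s2_e, seed, slope_sd = 0) {
  set.seed(seed)
  u <- rnorm(S, 0, sqrt(s2_sire))
  v <- rnorm(S, 0, slope_sd)
  x <- runif(S * k, 60, 80)
  s <- rep(seq_len(S), each = k)
  phi <- 2 * (x - 60) / 20 - 1
  y <- mu + u[s] + v[s] * phi + rnorm(S * k, 0, sqrt(s2_e))
  data.frame(animal = seq_len(S * k), sire = sprintf("s%03d", s),
             litter = "l1", batch = "b1", cf = 0, parity = 1,
             gender = "gilt", dam_line = 1, y = y, x = x)
}

id_kernel <- function(ids) {
  K <- diag(length(ids))
  dimnames(K) <- list(ids, ids)
  K
}

test_that("posterior variance ratio matches the one-way ANOVA estimator", {
  S <- 40L; k <- 25L
  dat <- oneway_data(S, k, mu = 5, s2_sire = 0.3, s2_e = 1, seed = 12L)
  sp <- rrm_spec("y", "x", n_iter = 2500L, burn_in = 500L, thin = 2L,
                 seed = 1L, residual_classes = 1L)
  fr <- suppressMessages(build_frame(dat, dat[c("animal", "x")], sp))
  fit <- gibbs_fit(fr, id_kernel(fr$sire_ids), sp)
  sm <- posterior_summary(fit)
  g00 <- sm$mean[sm$parameter == "g00"]
  s2e <- sm$mean[sm$parameter == "e_1"]

  av <- anova(lm(y ~ factor(sire), dat))
  msb <- av[1, "Mean Sq"]; msw <- av[2, "Mean Sq"]
  s2s_hat <- (msb - msw) / k
  expect_equal(g00 / (g00 + s2e), s2s_hat / (s2s_hat + msw),
               tolerance = 0.05)
})

test_that("null sire variance is recovered as near zero", {
  S <- 40L; k <- 15L
  dat <- oneway_data(S, k, mu = 2, s2_sire = 0, s2_e = 1, seed = 13L)
  sp <- rrm_spec("y", "x", n_iter = 2000L, burn_in = 500L, thin = 2L,
                 seed = 2L, residual_classes = 2L)
  fr <- suppressMessages(build_frame(dat, dat[c("animal", "x")], sp))
  fit <- gibbs_fit(fr, id_kernel(fr$sire_ids), sp)
  sm <- posterior_summary(fit)
  expect_lt(sm$mean[sm$parameter == "g00"], 0.07)
  expect_lt(sm$mean[sm$parameter == "g11"], 0.07)
  expect_lt(sm$q2.5[sm$parameter == "g00"], 0.02)
})

test_that("full-model simulation recovers every component within 3 posterior SDs", {
  tr <- small_truth(n_offspring = 2500L, s2_int = 0.5, s2_slope = 0.12,
                    cov_int_slope = 0.1, s2_batch = 0.2, s2_litter = 0.3,
                    s2_e = 0.8, trait_mean = 20, seed = 14L)
  sim <- simulate_dataset(tr)
  sp <- rrm_spec("cBF", "rh_92_122", n_iter = 3000L, burn_in = 1000L,
                 thin = 2L, seed = 3L)
  fr <- build_frame(sim$phen, sim$heatload, sp)
  A <- a_matrix(sim$structure$pedigree)
  fit <- gibbs_fit(fr, sire_block(A, fr$sire_ids), sp)
  sm <- posterior_summary(fit)
  truth_vals <- c(g00 = 0.5, g01 = 0.1, g11 = 0.12, batch = 0.2,
                  litter = 0.3, e_5 = 0.8)
  for (p in names(truth_vals)) {
    row <- sm[sm$parameter == p, ]
    expect_lt(abs(row$mean - truth_vals[[p]]), 3 * row$sd + 1e-8,
              label = paste("component", p))
  }
  # fixed covariate regression recovered too
  beta_true <- attr(sim$phen, "truth_effects")$beta
  rowb <- sm[sm$parameter == "p1", ]
  expect_lt(abs(rowb$mean - beta_true), 4 * rowb$sd)
})

test_that("sire label permutation permutes solutions (up to Monte-Carlo error)", {
  S <- 30L; k <- 20L
  dat <- oneway_data(S, k, mu = 0, s2_sire = 0.6, s2_e = 0.5, seed = 15L,
                     slope_sd = 0.2)
  ped <- data.frame(animal = sprintf("s%03d", 1:S), sire = NA, dam = NA)
  K <- a_matrix(ped)
  sp <- rrm_spec("y", "x", n_iter = 2500L, burn_in = 500L, thin = 2L,
                 seed = 4L, residual_classes = 1L)
  fr <- suppressMessages(build_frame(dat, dat[c("animal", "x")], sp))
  fit1 <- gibbs_fit(fr, K, sp)
  sol1 <- sire_solutions(fit1)

  # relabel sires so their sort order is permuted, refit with permuted K
  relab <- setNames(sprintf("z%03d", sample(S)), sprintf("s%03d", 1:S))
  dat2 <- dat
  dat2$sire <- relab[dat$sire]
  K2 <- K
  dimnames(K2) <- list(relab[rownames(K)], relab[colnames(K)])
  fr2 <- suppressMessages(build_frame(dat2, dat2[c("animal", "x")], sp))
  fit2 <- gibbs_fit(fr2, K2, sp)
  sol2 <- sire_solutions(fit2)

  m <- match(relab[sol1$sire], sol2$sire)
  expect_gt(cor(sol1$a0, sol2$a0[m]), 0.98)
  expect_lt(max(abs(sol1$a0 - sol2$a0[m])), 0.15)
})

test_that("a fixed seed reproduces draws exactly and summaries behave", {
  S <- 15L; k <- 8L
  dat <- oneway_data(S, k, mu = 1, s2_sire = 0.4, s2_e = 0.6, seed = 16L)
  sp <- rrm_spec("y", "x", n_iter = 400L, burn_in = 100L, thin = 3L,
                 seed = 5L, residual_classes = 2L)
  fr <- suppressMessages(build_frame(dat, dat[c("animal", "x")], sp))
  K <- id_kernel(fr$sire_ids)
  fit1 <- gibbs_fit(fr, K, sp)
  fit2 <- gibbs_fit(fr, K, sp)
  expect_identical(fit1$G, fit2$G)
  expect_identical(fit1$sire, fit2$sire)
  expect_equal(nrow(fit1$G), n_retained(sp))

  sm <- posterior_summary(fit1, include_sires = TRUE)
  expect_true(all(c("g00", "batch", "e_1", "e_2") %in% sm$parameter))
  expect_true(all(sm$ess > 0 & sm$ess <= nrow(fit1$G) + 1e-8))
  expect_true(all(sm$q2.5 <= sm$mean & sm$mean <= sm$q97.5))
})
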