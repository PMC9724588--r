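random_h <- function(j = 20, theta = 0.2, seed = 1) {
  set.seed(seed)
  x <- rnorm(j, 0.1, 0.03)
  x[x == 0] <- 0.01
  sx <- runif(j, 0.005, 0.02)
  sy <- runif(j, 0.02, 0.08)
  y <- theta * x + rnorm(j, 0, sy)
  mr_input(x, sx, y, sy)
}

test_that("Wald ratio point estimate and first/second-order SEs", {
  w <- wald_ratio(1, 0.1, 0.2, 0.05)
  expect_equal(w$theta, 0.2)
  expect_equal(w$se, 0.05)
  w2 <- wald_ratio(-0.5, 0.1, 0.1, 0.05)
  expect_equal(w2$theta, -0.2)
  expect_equal(w2$se, 0.1)
  expect_error(wald_ratio(0, 0.1, 0.1, 0.05), "undefined")
  # second-order reduces to first-order as se_x -> 0
  a <- wald_ratio(0.5, 1e-9, 0.1, 0.05, second_order = TRUE)
  b <- wald_ratio(0.5, 1e-9, 0.1, 0.05)
  expect_equal(a$se, b$se, tolerance = 1e-10)
  # and exceeds it when se_x > 0
  c2 <- wald_ratio(0.5, 0.2, 0.1, 0.05, second_order = TRUE)
  expect_gt(c2$se, b$se)
})

test_that("IVW on homogeneous ratios returns the ratio with Q = 0", {
  h <- mr_input(c(1, 2, 4), rep(0.01, 3), c(0.2, 0.4, 0.8),
                c(1, 2, 4) * 0.05)  # equal ratio SEs -> equal weights
  fe <- mr_ivw(h, "fixed")
  re <- mr_ivw(h, "random")
  expect_equal(fe$theta, 0.2)
  expect_equal(re$theta, 0.2)
  expect_equal(fe$diagnostics$q, 0)
  expect_equal(fe$diagnostics$q_pval, 1)
})

test_that("IVW equals the origin-constrained WLS oracle", {
  for (seed in 1:5) {
    h <- random_h(20, seed = seed)
    v <- list(x = h$beta_exposure, y = h$beta_out, sy = h$se_out)
    fit <- lm(v$y ~ 0 + v$x, weights = 1 / v$sy^2)
    est <- mr_ivw(h, "fixed")
    expect_equal(est$theta, unname(coef(fit)), tolerance = 1e-10)
    # random-effects SE equals the WLS slope SE (sigma not truncated)
    re <- mr_ivw(h, "random")
    expect_equal(re$se, summary(fit)$coefficients[1, 2], tolerance = 1e-10)
  }
})

test_that("IVW is invariant to SNP order and joint sign flips", {
  h <- random_h(15, seed = 3)
  base <- mr_ivw(h)
  perm <- mr_ivw(h[sample(nrow(h)), ])
  expect_equal(perm$theta, base$theta)
  flip <- mr_input(-h$beta_exposure, h$se_exposure, -h$beta_out, h$se_out)
  expect_equal(mr_ivw(flip)$theta, base$theta)
})

test_that("fixed and random IVW share theta; SE ordering follows Q vs J-1", {
  h <- random_h(25, seed = 8)
  fe <- mr_ivw(h, "fixed")
  re <- mr_ivw(h, "random")
  expect_equal(fe$theta, re$theta)
  q <- fe$diagnostics$q
  j <- fe$n_snp
  expect_equal(re$se >= fe$se, q >= j - 1)
})

test_that("Egger matches the WLS oracle on oriented data", {
  set.seed(11)
  j <- 30
  x <- rnorm(j, 0, 0.05)
  x[x == 0] <- 0.01
  sy <- runif(j, 0.02, 0.08)
  y <- 0.01 * sign(x) + 0.3 * x + rnorm(j, 0, sy)
  h <- mr_input(x, rep(0.01, j), y, sy)
  eg <- mr_egger(h)
  fit <- lm(I(sign(x) * y) ~ abs(x), weights = 1 / sy^2)
  sm <- summary(fit)$coefficients
  expect_equal(eg$slope$theta, unname(coef(fit)[2]), tolerance = 1e-10)
  expect_equal(eg$intercept$theta, unname(coef(fit)[1]), tolerance = 1e-10)
  expect_equal(eg$slope$se, sm[2, 2], tolerance = 1e-10)
  expect_equal(eg$intercept$se, sm[1, 2], tolerance = 1e-10)
})

test_that("Egger recovers slope and intercept from near-noiseless data", {
  set.seed(4)
  x <- seq(0.02, 0.2, length.out = 10)
  y <- 0.005 + 0.3 * x + rnorm(10, 0, 1e-6)
  h <- mr_input(x, rep(0.01, 10), y, rep(0.05, 10))
  eg <- mr_egger(h)
  expect_equal(eg$slope$theta, 0.3, tolerance = 1e-4)
  expect_equal(eg$intercept$theta, 0.005, tolerance = 1e-4)
})

test_that("Egger with the intercept constrained to zero reproduces IVW", {
  h <- random_h(20, seed = 21)
  flip <- sign(h$beta_exposure) < 0
  x <- abs(h$beta_exposure)
  y <- ifelse(flip, -h$beta_out, h$beta_out)
  fit0 <- lm(y ~ 0 + x, weights = 1 / h$se_out^2)
  expect_equal(unname(coef(fit0)), mr_ivw(h)$theta, tolerance = 1e-12)
})

test_that("weighted median handles the textbook cases", {
  h <- mr_input(c(1, 1, 1), rep(0.01, 3), c(0.1, 0.2, 0.9), rep(1, 3))
  wm <- mr_weighted_median(h, n_boot = 100, seed = 5)
  expect_equal(wm$theta, 0.2)
  # weight concentrated on one ratio returns that ratio
  h2 <- mr_input(c(1, 1, 1), rep(0.01, 3), c(0.1, 0.2, 0.9),
                 c(1, 1 / sqrt(49), 1))  # middle ratio carries 98% weight
  wm2 <- mr_weighted_median(h2, n_boot = 100, seed = 5)
  expect_equal(wm2$theta, 0.2, tolerance = 1e-6)
  expect_error(mr_weighted_median(h), "seed")
})

test_that("equal-weight weighted median equals the ordinary median", {
  for (j in c(5, 8, 11)) {
    set.seed(j)
    ratios <- rnorm(j)
    h <- mr_input(rep(1, j), rep(0.01, j), ratios, rep(1, j))
    wm <- mr_weighted_median(h, n_boot = 100, seed = 2)
    expect_equal(wm$theta, median(ratios))
  }
})

test_that("weighted-median bootstrap SE is seeded and reproducible", {
  h <- random_h(12, seed = 31)
  a <- mr_weighted_median(h, n_boot = 200, seed = 99)
  b <- mr_weighted_median(h, n_boot = 200, seed = 99)
  expect_identical(a$se, b$se)
  expect_gt(a$se, 0)
})

test_that("Cochran's Q matches hand computation and boundary cases", {
  h <- mr_input(c(1, 2, 4), rep(0.01, 3), c(0.2, 0.4, 0.8), c(1, 2, 4) * 0.05)
  q0 <- cochran_q(h)
  expect_equal(q0$q, 0)
  expect_equal(q0$pval, 1)
  # two SNPs, ratios {0, 1}, ratio SEs 1: Q = 2 * 0.5^2 = 0.5, df 1
  h2 <- mr_input(c(1, 1), rep(0.01, 2), c(0, 1), c(1, 1))
  q2 <- cochran_q(h2)
  expect_equal(q2$q, 0.5)
  expect_equal(q2$df, 1L)
})

test_that("Q is approximately chi-square(J-1) under valid instruments", {
  j <- 12
  qs <- vapply(1:400, function(s) {
    study <- simulate_two_sample(sim_config(n_snp = j, seed = 10000 + s))
    cochran_q(sim_input(study))$q
  }, numeric(1))
  expect_equal(mean(qs), j - 1, tolerance = 3 * sqrt(2 * (j - 1) / 400) / (j - 1))
})

test_that("leave-one-out returns one row per SNP and finds the outlier", {
  h <- mr_input(c(1, 2, 4), rep(0.01, 3), c(0.2, 0.4, 0.8), c(1, 2, 4) * 0.05)
  loo <- mr_leave_one_out(h)
  expect_equal(nrow(loo), 3)
  expect_equal(loo$b, rep(0.2, 3))  # identical instruments: no influence

  study <- simulate_two_sample(sim_config(n_snp = 15, n_outliers = 1,
                                          outlier_magnitude = 15, seed = 44))
  hh <- sim_input(study)
  loo2 <- mr_leave_one_out(hh)
  expect_equal(nrow(loo2), 15)
  expect_equal(loo2$snp[loo2$rank == 1], study$truth$outlier_ids)
})

test_that("IVW 95% CI coverage sits in the binomial 99% band", {
  theta <- log(1.19)
  hits <- vapply(1:1000, function(s) {
    study <- simulate_two_sample(sim_config(n_snp = 60, seed = 20000 + s))
    e <- mr_ivw(sim_input(study))
    e$ci_low <= theta && theta <= e$ci_high
  }, logical(1))
  band <- 2.576 * sqrt(0.95 * 0.05 / 1000)
  expect_gt(mean(hits), 0.95 - band)
  expect_lt(mean(hits), 0.95 + band)
})

test_that("tidy output carries the forest-plot layout and OR scale", {
  h <- random_h(10, seed = 61)
  td <- tidy(mr_ivw(h))
  expect_named(td, c("method", "exposure", "outcome", "adjusted_for", "nsnp",
                     "b", "se", "ci_low", "ci_high", "pval", "or",
                     "or_ci_low", "or_ci_high"))
  expect_equal(td$or, exp(td$b))
  expect_equal(td$or_ci_low, exp(td$ci_low))
  # p-values are two-sided normal
  expect_equal(td$pval, 2 * pnorm(-abs(td$b / td$se)))
  all_td <- mr_all_methods(h, n_boot = 100, seed = 3)
  expect_setequal(all_td$method, c("ivw_fe", "ivw_mre", "egger_slope",
                                   "egger_intercept", "weighted_median"))
})

test_that("plot functions return ggplot objects", {
  h <- random_h(10, seed = 71)
  expect_s3_class(plot_forest(mr_all_methods(h, n_boot = 100, seed = 2)),
                  "ggplot")
  expect_s3_class(autoplot(mr_leave_one_out(h)), "ggplot")
  expect_s3_class(plot_mr_scatter(h), "ggplot")
})
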