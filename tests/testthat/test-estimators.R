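# Wald ratio, IVW, MR-Egger, weighted median.

test_that("Wald ratio is the effect quotient with first-order SE", {
  p <- make_pairs(0.5, 0.1, 0.05)
  est <- wald_ratio(p)
  expect_equal(est$beta, 0.2)
  expect_equal(est$se, 0.1)

  neg <- wald_ratio(make_pairs(-0.5, 0.1, 0.05))
  expect_equal(neg$beta, -0.2)
  expect_equal(neg$se, 0.1)

  null <- wald_ratio(make_pairs(1, 0, 0.03))
  expect_equal(null$beta, 0)
  expect_equal(null$pval, 1)

  expect_error(wald_ratio(make_pairs(0, 0.1, 0.05)),
               class = "medimr_degenerate_error")

  # second-order SE adds the exposure-side variance term
  p2 <- make_pairs(0.5, 0.1, 0.05, se_exp = 0.1)
  expect_equal(wald_ratio(p2, second_order = TRUE)$se,
               sqrt(0.05^2 / 0.25 + 0.01 * 0.01 / 0.0625))
})

test_that("IVW reduces to the Wald ratio for one SNP and matches hand arithmetic for two", {
  p1 <- make_pairs(0.5, 0.1, 0.05)
  expect_equal(ivw(p1, "fixed")$beta, wald_ratio(p1)$beta)
  expect_equal(ivw(p1, "fixed")$se, wald_ratio(p1)$se)
  expect_error(ivw(p1, "multiplicative_random"),
               class = "medimr_insufficient_instruments_error")

  p2 <- make_pairs(c(1, 1), c(0.1, 0.3), c(1, 1))
  fe <- ivw(p2, "fixed")
  expect_equal(fe$beta, 0.2)
  expect_equal(fe$se, 1 / sqrt(2))
  # Q = 0.02 < df = 1, so the multiplicative-random SE hits the floor
  mre <- ivw(p2, "multiplicative_random")
  expect_equal(mre$se, fe$se)
  expect_equal(cochran_q(p2)$Q, 0.02)
})

test_that("exact proportionality gives the common slope with zero heterogeneity", {
  p <- make_pairs(c(0.2, 0.5, 1.1), 0.3 * c(0.2, 0.5, 1.1), c(0.01, 0.02, 0.05))
  est <- ivw(p, "fixed")
  expect_equal(est$beta, 0.3)
  expect_equal(cochran_q(p)$Q, 0)
})

test_that("IVW equals the analytic weighted mean of ratios and a WLS oracle", {
  set.seed(201)
  for (i in 1:50) {
    J <- sample(3:30, 1)
    p <- make_pairs(rnorm(J, 0.2, 0.1) + 0.05, rnorm(J, 0.05, 0.05),
                    runif(J, 0.01, 0.2))
    est <- ivw(p, "fixed")
    w <- p$beta_exp^2 / p$se_out^2
    expect_equal(est$beta, sum(w * p$beta_out / p$beta_exp) / sum(w),
                 tolerance = 1e-12)
    # WLS of beta_out on beta_exp through the origin, weights 1/se_out^2
    fit <- lm(beta_out ~ 0 + beta_exp, data = p, weights = 1 / p$se_out^2)
    expect_equal(est$beta, unname(coef(fit)), tolerance = 1e-10)
  }
})

test_that("multiplicative random-effects SE is never below fixed-effects SE", {
  set.seed(202)
  for (i in 1:20) {
    J <- sample(2:25, 1)
    p <- make_pairs(rnorm(J, 0.3, 0.1) + 0.05, rnorm(J, 0.1, 0.1),
                    runif(J, 0.01, 0.3))
    expect_gte(ivw(p, "multiplicative_random")$se, ivw(p, "fixed")$se)
  }
})

test_that("estimators are equivariant under joint instrument sign flips", {
  set.seed(203)
  J <- 12
  p <- make_pairs(rnorm(J, 0.3, 0.1) + 0.05, rnorm(J, 0.1, 0.1),
                  runif(J, 0.01, 0.3))
  flip <- p
  s <- sample(c(-1, 1), J, replace = TRUE)
  flip$beta_exp <- flip$beta_exp * s
  flip$beta_out <- flip$beta_out * s
  expect_equal(ivw(flip)$beta, ivw(p)$beta, tolerance = 1e-14)
  expect_equal(mr_egger(flip)$slope$beta, mr_egger(p)$slope$beta,
               tolerance = 1e-14)
  expect_equal(mr_egger(flip)$intercept$beta, mr_egger(p)$intercept$beta,
               tolerance = 1e-14)
  expect_equal(weighted_median(flip, n_boot = 50, seed = 5)$beta,
               weighted_median(p, n_boot = 50, seed = 5)$beta,
               tolerance = 1e-14)
})

test_that("MR-Egger recovers an exact affine relation and flags no pleiotropy on a line through zero", {
  g <- c(0.1, 0.3, 0.5, 0.9)
  p <- make_pairs(g, 0.05 + 0.3 * g, c(0.01, 0.02, 0.03, 0.01))
  eg <- mr_egger(p)
  expect_equal(eg$slope$beta, 0.3, tolerance = 1e-12)
  expect_equal(eg$intercept$beta, 0.05, tolerance = 1e-12)

  p0 <- make_pairs(g, 0.3 * g, c(0.01, 0.02, 0.03, 0.01))
  eg0 <- mr_egger(p0)
  expect_equal(eg0$intercept$beta, 0, tolerance = 1e-12)
  expect_equal(eg0$intercept$pval, 1, tolerance = 1e-6)

  expect_error(mr_egger(make_pairs(c(1, 2), c(1, 2), c(1, 1))),
               class = "medimr_insufficient_instruments_error")
})

test_that("MR-Egger equals a generic weighted-least-squares solver", {
  set.seed(204)
  for (i in 1:50) {
    J <- sample(4:40, 1)
    p <- make_pairs(abs(rnorm(J, 0.3, 0.15)) + 0.01, rnorm(J, 0.1, 0.1),
                    runif(J, 0.01, 0.3))
    eg <- mr_egger(p)
    fit <- lm(beta_out ~ beta_exp, data = p, weights = 1 / p$se_out^2)
    expect_equal(eg$slope$beta, unname(coef(fit)[2]), tolerance = 1e-10)
    expect_equal(eg$intercept$beta, unname(coef(fit)[1]), tolerance = 1e-10)
    # with the residual scale floored at 1, SEs are lm's unscaled SEs times
    # max(1, sigma) = lm SE / min(1, sigma)
    sm <- summary(fit)
    expect_equal(eg$slope$se, sm$coefficients[2, 2] / min(1, sm$sigma),
                 tolerance = 1e-10)
  }
})

test_that("weighted median interpolates the cumulative-weight midpoint", {
  # equal weights, odd J: the plain median exactly
  p <- make_pairs(c(1, 1, 1), c(0.1, 0.2, 0.9), c(1, 1, 1))
  expect_equal(weighted_median(p, n_boot = 50, seed = 1)$beta, 0.2)

  set.seed(205)
  J <- 7
  ratios <- rnorm(J)
  p2 <- make_pairs(rep(1, J), ratios, rep(1, J))
  expect_equal(weighted_median(p2, n_boot = 50, seed = 1)$beta,
               median(ratios))

  expect_error(weighted_median(make_pairs(c(1, 1), c(0.1, 0.3), c(1, 1)),
                               n_boot = 50, seed = 1),
               class = "medimr_insufficient_instruments_error")

  # dominant weight pulls the estimate into the heavy ratio's basin;
  # value fixed by the interpolation formula (hand computation)
  w <- c(0.9, 0.05, 0.05)
  p3 <- make_pairs(rep(1, 3), c(0.1, 0.5, 0.9), 1 / sqrt(w))
  expect_equal(weighted_median(p3, n_boot = 50, seed = 1)$beta,
               0.1421052632, tolerance = 1e-9)
})

test_that("weighted median bootstrap is seeded and reproducible", {
  set.seed(206)
  p <- make_pairs(abs(rnorm(9, 0.3, 0.1)) + 0.05, rnorm(9, 0.1, 0.05),
                  runif(9, 0.02, 0.1), se_exp = 0.02)
  a <- weighted_median(p, n_boot = 200, seed = 42)
  b <- weighted_median(p, n_boot = 200, seed = 42)
  expect_identical(a$beta, b$beta)
  expect_identical(a$se, b$se)
  expect_gt(a$se, 0)
  expect_equal(a$seed, 42L)
  expect_error(weighted_median(p, n_boot = 10), class = "medimr_config_error")
})

test_that("p-values recovered from printed OR tables match the normal formula", {
  expect_equal(signif(wald_p_from_or_ci(0.888, 0.824, 0.958), 2), 0.0020)
  expect_equal(wald_p_from_or_ci(1.0, 0.9, 1 / 0.9), 1)
  # frozen from an independent scripted normal-CDF computation
  expect_equal(wald_p_from_or_ci(2.0, 1.5, 2.667), 2.34281613452e-06,
               tolerance = 1e-9)
})

test_that("under directional InSIDE pleiotropy MR-Egger is less biased than IVW", {
  reps <- 500
  bias_ivw <- bias_egger <- numeric(reps)
  for (r in seq_len(reps)) {
    sim <- simulate_sumstats(sim_config(J = 100, J_m = 0, seed = 40000 + r,
                                        pleio_mean = 0.002, pleio_sd = 0.001))
    h <- harmonize(sim$exposure, sim$outcome)
    bias_ivw[r] <- ivw(h)$beta - sim$truth$tau_true
    bias_egger[r] <- mr_egger(h)$slope$beta - sim$truth$tau_true
  }
  expect_gt(abs(mean(bias_ivw)), abs(mean(bias_egger)))
  expect_gt(abs(mean(bias_ivw)), 0.01)  # IVW is materially biased here
})
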