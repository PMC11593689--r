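# Product-of-coefficients mediation, delta-method SEs, filters, BH-FDR.

test_that("delta-method product SE matches hand arithmetic and flags the degenerate point", {
  expect_equal(delta_se_product(1, 0, 0.7, 0.2), 0.2)
  expect_equal(delta_se_product(0.2, 0.05, 0.5, 0.1), sqrt(0.001025))
  expect_warning(se0 <- delta_se_product(0, 0.1, 0, 0.1), "degenerate")
  expect_equal(se0, 0)
  expect_error(delta_se_product(1, -0.1, 1, 0.1), class = "medimr_domain_error")
})

test_that("delta-method proportion SE matches hand arithmetic with its degenerate fallback", {
  expect_equal(delta_se_proportion(1, 0, 1, 0, 1, 0), 0)
  expect_equal(delta_se_proportion(1, 0.1, 1, 0.1, 1, 0.1), sqrt(0.03))
  # a = 0: falls back to the product SE over |tau|
  expect_equal(delta_se_proportion(0, 0.05, 0.5, 0.1, 0.2, 0.02),
               sqrt(0.5^2 * 0.05^2) / 0.2)
  expect_error(delta_se_proportion(1, 0.1, 1, 0.1, 0, 0.1),
               class = "medimr_domain_error")
})

test_that("proportion and its CI are invariant to a common rescaling of all effects", {
  set.seed(401)
  for (i in 1:20) {
    a <- rnorm(1, 0.2, 0.1); b <- rnorm(1, 0.3, 0.1); tau <- rnorm(1, 0.3, 0.1)
    if (tau == 0 || a == 0 || b == 0) next
    ses <- abs(rnorm(3, 0.05, 0.02))
    c_ <- runif(1, 0.1, 10)
    s1 <- delta_se_proportion(a, ses[1], b, ses[2], tau, ses[3])
    # rescaling all effects and SEs by c scales the proportion (= c^2/c)
    # and its SE by the same factor, so the relative CI is unchanged
    s2 <- delta_se_proportion(c_ * a, c_ * ses[1], c_ * b, c_ * ses[2],
                              c_ * tau, c_ * ses[3])
    expect_equal(s2, c_ * s1, tolerance = 1e-10)
    expect_equal(s2 / abs(c_ * a * b / tau), s1 / abs(a * b / tau),
                 tolerance = 1e-10)
  }
})

mk_est <- function(beta, se) {
  df <- data.frame(method = "ivw_mre", beta = beta, se = se,
                   ci_low = beta - 1.96 * se, ci_high = beta + 1.96 * se,
                   pval = 2 * pnorm(-abs(beta / se)), n_snp = 10L,
                   or_point = exp(beta), or_low = NA, or_high = NA)
  class(df) <- c("mr_estimate", "data.frame")
  df
}

test_that("two-step decomposition reproduces the scripted oracle values", {
  med <- two_step_mediation(mk_est(0.1, 0.02), mk_est(-0.121, 0.03),
                            mk_est(-0.1, 0.02))
  # frozen from an independent arithmetic script
  expect_equal(med$indirect, -0.0121)
  expect_equal(med$se_indirect, 0.0038544001, tolerance = 1e-7)
  expect_equal(med$proportion, 0.121)
  expect_equal(med$se_proportion, 0.0455113173, tolerance = 1e-7)
  expect_equal(med$ci_low_prop, 0.03179946, tolerance = 1e-7)
  expect_equal(med$ci_high_prop, 0.21020054, tolerance = 1e-7)
  expect_equal(med$z, -3.13926934, tolerance = 1e-7)
  expect_equal(med$pval, 0.001693697, tolerance = 1e-7)
  expect_true(med$consistent)
  # exact identities
  expect_equal(med$direct + med$indirect, med$tau, tolerance = 1e-12)
  expect_equal(med$z * med$se_indirect, med$indirect, tolerance = 1e-12)
})

test_that("null step-1 effect gives zero mediation, trivially consistent", {
  med <- two_step_mediation(mk_est(0, 0.02), mk_est(0.5, 0.03),
                            mk_est(0.2, 0.02))
  expect_equal(med$indirect, 0)
  expect_equal(med$proportion, 0)
  expect_true(med$consistent)
  expect_equal(med$pval, 1)
})

test_that("indirect effects opposing the total effect are marked inconsistent", {
  med <- two_step_mediation(mk_est(0.2, 0.01), mk_est(0.3, 0.01),
                            mk_est(-0.1, 0.01))
  expect_false(med$consistent)
})

test_that("tau = 0 leaves the proportion undefined but keeps the indirect effect", {
  expect_warning(med <- two_step_mediation(mk_est(0.2, 0.01), mk_est(0.3, 0.01),
                                           mk_est(0, 0.01)), "tau")
  expect_true(is.na(med$proportion))
  expect_equal(med$indirect, 0.06)
})

test_that("decomposition is exact over random instances", {
  set.seed(402)
  for (i in 1:50) {
    med <- two_step_mediation(mk_est(rnorm(1), runif(1, 0.01, 1)),
                              mk_est(rnorm(1), runif(1, 0.01, 1)),
                              mk_est(rnorm(1) + 0.01, runif(1, 0.01, 1)))
    expect_equal(med$direct + med$indirect, med$tau, tolerance = 1e-12)
  }
})

test_that("delta product SE matches Monte-Carlo spread for strong effects", {
  set.seed(403)
  configs <- list(c(0.5, 0.05, 0.3, 0.05), c(1, 0.1, -2, 0.2),
                  c(-0.4, 0.1, 0.9, 0.2))
  for (cf in configs) {
    draws <- rnorm(20000, cf[1], cf[2]) * rnorm(20000, cf[3], cf[4])
    expect_equal(delta_se_product(cf[1], cf[2], cf[3], cf[4]), sd(draws),
                 tolerance = 0.1)
  }
})

test_that("the consistency filter applies direction and significance screens", {
  strong <- as.data.frame(two_step_mediation(mk_est(0.3, 0.02),
                                             mk_est(0.4, 0.02),
                                             mk_est(0.2, 0.02)))
  wrong_dir <- as.data.frame(two_step_mediation(mk_est(0.3, 0.02),
                                                mk_est(0.4, 0.02),
                                                mk_est(-0.2, 0.02)))
  weak <- as.data.frame(two_step_mediation(mk_est(0.02, 0.015),
                                           mk_est(0.4, 0.02),
                                           mk_est(0.2, 0.02)))
  res <- rbind(strong, wrong_dir, weak)
  kept <- consistency_filter(res, alpha = 0.05)
  expect_equal(nrow(kept), 1L)
  expect_equal(kept$a, 0.3)
  removed <- attr(kept, "removed")
  expect_equal(nrow(removed), 2L)
  expect_match(removed$reason[1], "inconsistent")

  # all-consistent input is the identity
  allg <- rbind(strong, strong)
  expect_equal(nrow(consistency_filter(allg)), 2L)

  # consistent but non-significant mediation p is removed
  marginal <- strong
  marginal$pval <- 0.2
  expect_equal(nrow(consistency_filter(rbind(marginal))), 0L)
})

test_that("BH adjustment matches a brute-force step-up oracle on small inputs", {
  expect_equal(bh_fdr(0.05), 0.05)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_error(bh_fdr(c(0.5, 0)), class = "medimr_domain_error")
  expect_error(bh_fdr(c(0.5, 1.2)), class = "medimr_domain_error")

  # oracle: q_i = the smallest level at which BH step-up rejects H_i
  bh_reject <- function(p, level) {
    m <- length(p)
    ord <- order(p)
    k <- which(p[ord] <= seq_len(m) * level / m)
    rejected <- logical(m)
    if (length(k) > 0) rejected[ord[seq_len(max(k))]] <- TRUE
    rejected
  }
  brute_q <- function(p) {
    m <- length(p)
    cand <- sort(unique(as.vector(outer(p, seq_len(m), function(pp, j) pp * m / j))))
    vapply(seq_len(m), function(i) {
      min(cand[vapply(cand, function(a) bh_reject(p, a)[i], logical(1))])
    }, numeric(1))
  }
  set.seed(404)
  for (m in 1:6) {
    for (rep in 1:10) {
      p <- runif(m)
      expect_equal(bh_fdr(p), pmin(1, brute_q(p)), tolerance = 1e-12)
    }
  }
})

test_that("Monte-Carlo proportion CI agrees with the delta interval for precise estimates", {
  mc <- mediation_mc_ci(0.1, 0.005, -0.121, 0.006, -0.1, 0.004,
                        n_sim = 5e4, seed = 9)
  med <- two_step_mediation(mk_est(0.1, 0.005), mk_est(-0.121, 0.006),
                            mk_est(-0.1, 0.004))
  expect_equal(mc$ci_low, med$ci_low_prop, tolerance = 0.01)
  expect_equal(mc$ci_high, med$ci_high_prop, tolerance = 0.01)
  expect_identical(mediation_mc_ci(0.1, 0.005, -0.121, 0.006, -0.1, 0.004,
                                   n_sim = 1000, seed = 9)$seed, 9L)
})
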