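# Two-step mediation MR: product-of-coefficients decomposition with
# delta-method uncertainty, proportion mediated, consistency filter, BH-FDR.

#' Delta-method standard error of a product of independent estimates
#'
#' First-order approximation for `a * b` with independent errors:
#' `se = sqrt(a^2 se_b^2 + b^2 se_a^2)`. Degenerate at `a = b = 0`, where
#' the first-order term vanishes (a warning is issued and 0 returned).
#'
#' @param a,b Point estimates.
#' @param se_a,se_b Their standard errors (non-negative).
#' @return Standard error of the product.
#' @export
delta_se_product <- function(a, se_a, b, se_b) {
  if (se_a < 0 || se_b < 0) {
    stop_medimr("standard errors must be non-negative", "medimr_domain_error")
  }
  if (a == 0 && b == 0) {
    warning("delta_se_product: a = b = 0 is a degenerate first-order point")
  }
  sqrt(a^2 * se_b^2 + b^2 * se_a^2)
}

#' Delta-method standard error of a proportion mediated
#'
#' First-order SE of `P = a*b/tau` assuming independence of the three
#' estimates (non-overlapping samples):
#' `se = |P| * sqrt(se_a^2/a^2 + se_b^2/b^2 + se_tau^2/tau^2)`. When `a` or
#' `b` is zero the relative form degenerates and the product SE divided by
#' `|tau|` is used instead.
#'
#' @inheritParams delta_se_product
#' @param tau,se_tau Total-effect estimate and SE; `tau` must be non-zero.
#' @return Standard error of the proportion.
#' @export
delta_se_proportion <- function(a, se_a, b, se_b, tau, se_tau) {
  if (se_a < 0 || se_b < 0 || se_tau < 0) {
    stop_medimr("standard errors must be non-negative", "medimr_domain_error")
  }
  if (tau == 0) {
    stop_medimr("proportion mediated undefined for tau = 0", "medimr_domain_error")
  }
  if (a == 0 || b == 0) {
    return(sqrt(a^2 * se_b^2 + b^2 * se_a^2) / abs(tau))
  }
  P <- a * b / tau
  abs(P) * sqrt(se_a^2 / a^2 + se_b^2 / b^2 + se_tau^2 / tau^2)
}

#' Two-step mediation decomposition
#'
#' Combines three univariable two-sample MR estimates — `a` (exposure to
#' mediator), `b` (mediator to outcome, from the mediator's own
#' instruments) and `tau` (total exposure-to-outcome effect) — into the
#' product-of-coefficients decomposition: indirect effect `a*b` with
#' delta-method SE, direct effect `tau - a*b` (so direct + indirect always
#' equals the total exactly), proportion mediated `a*b/tau` with a
#' delta-method confidence interval, and a Z statistic for the indirect
#' effect (`Z = indirect / se_indirect`, two-sided normal p). The
#' `consistent` flag records whether the indirect effect has the same sign
#' as the total effect (trivially true when the indirect effect is zero).
#' All effects must be on a common (linear or log-odds) scale.
#'
#' @param effect_xm,effect_my,effect_xy `mr_estimate` rows for the
#'   exposure-mediator, mediator-outcome and exposure-outcome effects.
#' @param level CI coverage for the proportion.
#' @param test `"indirect"` (default) tests the indirect effect; on
#'   `"proportion"` the Z/p refer to the proportion mediated instead.
#' @return A one-row `mediation_result` data.frame with columns `a`,
#'   `se_a`, `p_a`, `b`, `se_b`, `p_b`, `tau`, `se_tau`, `p_tau`,
#'   `indirect`, `se_indirect`, `direct`, `proportion`, `se_proportion`,
#'   `ci_low_prop`, `ci_high_prop`, `z`, `pval`, `consistent`. When
#'   `tau = 0` the proportion columns are NA and the indirect effect is
#'   still returned.
#' @export
two_step_mediation <- function(effect_xm, effect_my, effect_xy, level = 0.95,
                               test = c("indirect", "proportion")) {
  test <- match.arg(test)
  a <- effect_xm$beta; se_a <- effect_xm$se
  b <- effect_my$beta; se_b <- effect_my$se
  tau <- effect_xy$beta; se_tau <- effect_xy$se

  indirect <- a * b
  se_ind <- suppressWarnings(delta_se_product(a, se_a, b, se_b))
  direct <- tau - indirect

  if (tau != 0) {
    proportion <- indirect / tau
    se_prop <- delta_se_proportion(a, se_a, b, se_b, tau, se_tau)
    zq <- z_level(level)
    ci_lo <- proportion - zq * se_prop
    ci_hi <- proportion + zq * se_prop
  } else {
    warning("two_step_mediation: tau = 0, proportion mediated undefined")
    proportion <- se_prop <- ci_lo <- ci_hi <- NA_real_
  }

  if (test == "indirect") {
    z <- if (se_ind > 0) indirect / se_ind else if (indirect == 0) 0 else sign(indirect) * Inf
  } else {
    if (is.na(proportion)) {
      stop_medimr("cannot test the proportion when tau = 0", "medimr_domain_error")
    }
    z <- if (se_prop > 0) proportion / se_prop else if (proportion == 0) 0 else sign(proportion) * Inf
  }
  pval <- two_sided_p(z)
  consistent <- indirect == 0 || sign(indirect) == sign(tau)

  structure(data.frame(
    a = a, se_a = se_a, p_a = effect_xm$pval,
    b = b, se_b = se_b, p_b = effect_my$pval,
    tau = tau, se_tau = se_tau, p_tau = effect_xy$pval,
    indirect = indirect, se_indirect = se_ind, direct = direct,
    proportion = proportion, se_proportion = se_prop,
    ci_low_prop = ci_lo, ci_high_prop = ci_hi,
    z = z, pval = pval, consistent = consistent,
    stringsAsFactors = FALSE
  ), class = c("mediation_result", "data.frame"))
}

#' Filter mediation results for direction consistency and significance
#'
#' Retains results whose indirect effect acts in the same direction as the
#' total effect (`consistent`) and whose step-1, step-2 and mediation
#' p-values all fall below `alpha`. Removed rows and the reason for removal
#' are attached as attribute `removed`.
#'
#' @param results A data.frame of [two_step_mediation()] rows.
#' @param alpha Significance level (default 0.05).
#' @return The retained subset, same columns and order as the input.
#' @export
consistency_filter <- function(results, alpha = 0.05) {
  stopifnot(is.data.frame(results))
  if (nrow(results) == 0L) return(results)
  reason <- rep(NA_character_, nrow(results))
  reason[!results$consistent] <- "direction inconsistent with total effect"
  reason[is.na(reason) & results$p_a >= alpha] <- "step-1 (exposure-mediator) not significant"
  reason[is.na(reason) & results$p_b >= alpha] <- "step-2 (mediator-outcome) not significant"
  reason[is.na(reason) & results$pval >= alpha] <- "mediation effect not significant"
  keep <- is.na(reason)
  removed <- results[!keep, , drop = FALSE]
  removed$reason <- reason[!keep]
  out <- results[keep, , drop = FALSE]
  attr(out, "removed") <- removed
  out
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Standard step-up adjusted q-values (via [stats::p.adjust()]) with input
#' order preserved; validates that all p-values lie in (0, 1].
#'
#' @param pvals Numeric vector of p-values in (0, 1].
#' @return Adjusted q-values, same order as the input.
#' @export
bh_fdr <- function(pvals) {
  if (length(pvals) == 0L) return(numeric(0))
  if (any(!is.finite(pvals) | pvals <= 0 | pvals > 1)) {
    stop_medimr("p-values must lie in (0, 1]", "medimr_domain_error")
  }
  stats::p.adjust(pvals, method = "BH")
}

#' Monte-Carlo confidence interval for the proportion mediated
#'
#' Seeded cross-check for the delta-method interval: draws `a`, `b`, `tau`
#' from independent normals centred on their estimates and returns the
#' quantile interval of the simulated proportions.
#'
#' @inheritParams delta_se_proportion
#' @param n_sim Number of draws.
#' @param seed Mandatory integer seed.
#' @param level Interval coverage.
#' @return List with `ci_low`, `ci_high`, `se` (SD of the draws), `seed`.
#' @export
mediation_mc_ci <- function(a, se_a, b, se_b, tau, se_tau,
                            n_sim = 1e5, seed, level = 0.95) {
  if (missing(seed)) stop_medimr("mediation_mc_ci requires an explicit seed",
                                 "medimr_config_error")
  if (tau == 0) stop_medimr("proportion mediated undefined for tau = 0",
                            "medimr_domain_error")
  draws <- withr_seed(seed, {
    as_ <- stats::rnorm(n_sim, a, se_a)
    bs_ <- stats::rnorm(n_sim, b, se_b)
    ts_ <- stats::rnorm(n_sim, tau, se_tau)
    as_ * bs_ / ts_
  })
  qs <- stats::quantile(draws, c((1 - level) / 2, 1 - (1 - level) / 2),
                        names = FALSE)
  list(ci_low = qs[1], ci_high = qs[2], se = stats::sd(draws),
       seed = as.integer(seed))
}
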