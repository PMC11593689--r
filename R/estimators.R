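# Causal-effect estimators on harmonized instrument sets: Wald ratio,
# fixed / multiplicative-random-effects IVW, MR-Egger, weighted median.

new_mr_estimate <- function(method, beta, se, pval, n_snp, level = 0.95,
                            df = NULL, seed = NULL) {
  q <- if (is.null(df)) z_level(level) else stats::qt(1 - (1 - level) / 2, df)
  ci_low <- beta - q * se
  ci_high <- beta + q * se
  out <- data.frame(method = method, beta = beta, se = se,
                    ci_low = ci_low, ci_high = ci_high, pval = pval,
                    n_snp = as.integer(n_snp),
                    or_point = exp(beta), or_low = exp(ci_low),
                    or_high = exp(ci_high),
                    stringsAsFactors = FALSE)
  if (!is.null(seed)) out$seed <- as.integer(seed)
  structure(out, class = c("mr_estimate", "data.frame"))
}

# Per-SNP ratio estimates and IVW weights from a harmonized pair set.
# First-order Wald SE: se_out / |gamma| (exposure noise ignored; see
# wald_ratio(second_order=)). Weights w_j = gamma_j^2 / se_out_j^2.
.ratio_stats <- function(pairs) {
  p <- kept_pairs(pairs)
  if (any(p$beta_exp == 0)) {
    stop_medimr("degenerate instrument: exposure beta is zero",
                "medimr_degenerate_error")
  }
  list(snp_id = p$snp_id,
       b = p$beta_out / p$beta_exp,
       se = p$se_out / abs(p$beta_exp),
       w = p$beta_exp^2 / p$se_out^2,
       pairs = p)
}

#' Wald ratio estimate from a single instrument
#'
#' The per-SNP causal estimate: the SNP-outcome effect divided by the
#' SNP-exposure effect, with a first-order delta-method standard error
#' `se_out / |beta_exp|`. With `second_order = TRUE` the exposure
#' uncertainty is included:
#' `se^2 = se_out^2/beta_exp^2 + beta_out^2 se_exp^2 / beta_exp^4`.
#'
#' @param pair One harmonized pair: a one-row `harmonized_pairs` data.frame
#'   (see [harmonize()]).
#' @param second_order Include the exposure-side variance term.
#' @return An `mr_estimate` row.
#' @export
wald_ratio <- function(pair, second_order = FALSE) {
  p <- kept_pairs(pair)
  stopifnot(nrow(p) == 1L)
  if (p$beta_exp == 0) {
    stop_medimr("degenerate instrument: exposure beta is zero",
                "medimr_degenerate_error")
  }
  beta <- p$beta_out / p$beta_exp
  se <- if (second_order) {
    sqrt(p$se_out^2 / p$beta_exp^2 + p$beta_out^2 * p$se_exp^2 / p$beta_exp^4)
  } else {
    p$se_out / abs(p$beta_exp)
  }
  new_mr_estimate("wald", beta, se, two_sided_p(beta / se), 1L)
}

# Cochran's Q about the fixed-effects IVW slope (shared with sensitivity).
.cochran_q_stat <- function(rs) {
  beta_fe <- sum(rs$w * rs$b) / sum(rs$w)
  contrib <- rs$w * (rs$b - beta_fe)^2
  list(Q = sum(contrib), contributions = stats::setNames(contrib, rs$snp_id),
       beta_fe = beta_fe)
}

#' Inverse-variance-weighted causal estimate
#'
#' Meta-analysis of per-SNP Wald ratios with weights
#' \eqn{w_j = \gamma_j^2 / se_{\Gamma_j}^2}, equivalent to weighted least
#' squares of the outcome effects on the exposure effects through the
#' origin. The fixed-effects standard error is \eqn{(\sum w_j)^{-1/2}}; the
#' multiplicative random-effects model inflates it by
#' \eqn{\max(1, \sqrt{Q/(J-1)})} where Q is Cochran's Q, so its SE is never
#' smaller than the fixed-effects SE. P-values are two-sided normal.
#'
#' @param pairs Harmonized pairs ([harmonize()]); dropped pairs are ignored.
#' @param model `"multiplicative_random"` (default, requires at least two
#'   instruments) or `"fixed"` (at least one; with a single instrument the
#'   result equals the Wald ratio).
#' @param level CI coverage.
#' @return An `mr_estimate` row.
#' @export
ivw <- function(pairs, model = c("multiplicative_random", "fixed"),
                level = 0.95) {
  model <- match.arg(model)
  rs <- .ratio_stats(pairs)
  J <- length(rs$b)
  min_j <- if (model == "fixed") 1L else 2L
  if (J < min_j) {
    stop_medimr(sprintf("ivw(model='%s') needs at least %d instrument(s), got %d",
                        model, min_j, J), "medimr_insufficient_instruments_error")
  }
  beta <- sum(rs$w * rs$b) / sum(rs$w)
  se_fe <- 1 / sqrt(sum(rs$w))
  se <- se_fe
  if (model == "multiplicative_random") {
    Q <- .cochran_q_stat(rs)$Q
    se <- se_fe * max(1, sqrt(Q / (J - 1)))
  }
  method <- if (model == "fixed") "ivw_fe" else "ivw_mre"
  new_mr_estimate(method, beta, se, two_sided_p(beta / se), J, level)
}

#' MR-Egger regression
#'
#' Weighted least squares of the outcome effects on the exposure effects
#' with an intercept, weights \eqn{1/se_{\Gamma_j}^2}. Before fitting, each
#' pair is oriented so the exposure effect is non-negative (both effects
#' sign-flipped where needed); this orientation affects the intercept and is
#' part of the estimator's definition. Standard errors are scaled by
#' `max(1, residual scale)` and p-values come from the t distribution with
#' J - 2 degrees of freedom. A non-zero intercept indicates directional
#' horizontal pleiotropy (valid as a test under the InSIDE assumption).
#'
#' @inheritParams ivw
#' @return List with `mr_estimate` rows `slope` and `intercept`.
#' @export
mr_egger <- function(pairs, level = 0.95) {
  p <- kept_pairs(pairs)
  J <- nrow(p)
  if (J < 3L) {
    stop_medimr(sprintf("mr_egger needs at least 3 instruments, got %d", J),
                "medimr_insufficient_instruments_error")
  }
  flip <- sign(p$beta_exp)
  flip[flip == 0] <- 1
  x <- p$beta_exp * flip
  y <- p$beta_out * flip
  w <- 1 / p$se_out^2

  # Analytic WLS: solve (X'WX) theta = X'Wy for X = [1, x].
  sw <- sum(w); swx <- sum(w * x); swx2 <- sum(w * x^2)
  swy <- sum(w * y); swxy <- sum(w * x * y)
  det <- sw * swx2 - swx^2
  if (det <= 0) stop_medimr("degenerate design in MR-Egger", "medimr_degenerate_error")
  intercept <- (swx2 * swy - swx * swxy) / det
  slope <- (sw * swxy - swx * swy) / det
  resid <- y - intercept - slope * x
  sigma2 <- sum(w * resid^2) / (J - 2)
  scale <- max(1, sqrt(sigma2))
  se_int <- sqrt(swx2 / det) * scale
  se_slope <- sqrt(sw / det) * scale
  p_int <- 2 * stats::pt(-abs(intercept / se_int), df = J - 2)
  p_slope <- 2 * stats::pt(-abs(slope / se_slope), df = J - 2)
  list(slope = new_mr_estimate("egger_slope", slope, se_slope, p_slope, J,
                               level, df = J - 2),
       intercept = new_mr_estimate("egger_intercept", intercept, se_int,
                                   p_int, J, level, df = J - 2))
}

# Weighted median of ratio estimates b with weights w: sort ascending,
# normalize, interpolate at cumulative midpoint probability 0.5.
.weighted_median <- function(b, w) {
  ord <- order(b)
  b <- b[ord]; w <- w[ord] / sum(w)
  p <- cumsum(w) - w / 2
  if (p[1L] >= 0.5) return(b[1L])
  if (p[length(p)] <= 0.5) return(b[length(b)])
  stats::approx(p, b, xout = 0.5, ties = "ordered")$y
}

#' Weighted median causal estimate
#'
#' The inverse-variance weighted median of per-SNP Wald ratios: consistent
#' when at least half the weight comes from valid instruments. Sorted ratio
#' estimates are interpolated at the cumulative weight midpoint 0.5. The
#' standard error is the standard deviation of the estimate over `n_boot`
#' parametric bootstrap resamples in which each exposure and outcome effect
#' is redrawn from a normal distribution centred on its observed value with
#' its observed SE; the seed is mandatory and recorded in the output.
#'
#' @inheritParams ivw
#' @param n_boot Number of bootstrap resamples.
#' @param seed Integer seed for the bootstrap (recorded in the result).
#' @return An `mr_estimate` row with a `seed` column.
#' @export
weighted_median <- function(pairs, n_boot = 1000, seed, level = 0.95) {
  if (missing(seed)) stop_medimr("weighted_median requires an explicit seed",
                                 "medimr_config_error")
  rs <- .ratio_stats(pairs)
  J <- length(rs$b)
  if (J < 3L) {
    stop_medimr(sprintf("weighted_median needs at least 3 instruments, got %d", J),
                "medimr_insufficient_instruments_error")
  }
  est <- .weighted_median(rs$b, 1 / rs$se^2)
  p <- rs$pairs
  boot <- withr_seed(seed, {
    vapply(seq_len(n_boot), function(i) {
      ge <- stats::rnorm(J, p$beta_exp, p$se_exp)
      go <- stats::rnorm(J, p$beta_out, p$se_out)
      ok <- ge != 0
      bb <- go[ok] / ge[ok]
      ww <- 1 / (p$se_out[ok] / abs(ge[ok]))^2
      .weighted_median(bb, ww)
    }, numeric(1))
  })
  se <- stats::sd(boot)
  new_mr_estimate("weighted_median", est, se, two_sided_p(est / se), J,
                  level, seed = seed)
}

# Evaluate expr under a local RNG seed without disturbing the caller's RNG.
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

#' Two-sided p-value implied by a printed odds ratio and CI
#'
#' Recovers `(beta, se)` with [or_ci_to_logscale()] and returns
#' `2 * pnorm(-|beta/se|)` — a consistency check for published OR tables.
#'
#' @inheritParams or_ci_to_logscale
#' @return Two-sided p-value.
#' @export
#' @examples
#' wald_p_from_or_ci(0.888, 0.824, 0.958)  # ~2.0e-3
wald_p_from_or_ci <- function(or_point, ci_low, ci_high, level = 0.95) {
  bs <- or_ci_to_logscale(or_point, ci_low, ci_high, level)
  if (bs$se == 0) {
    if (bs$beta != 0) stop_medimr("zero-width CI with non-null estimate",
                                  "medimr_degenerate_error")
    return(1)
  }
  two_sided_p(bs$beta / bs$se)
}
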