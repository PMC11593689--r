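# Heterogeneity and pleiotropy diagnostics: Cochran's Q, MR-PRESSO global
# and outlier tests, leave-one-out analysis, combined sensitivity report.

#' Cochran's Q heterogeneity test
#'
#' Q = \eqn{\sum_j w_j (\beta_j - \hat\beta_{IVW,fe})^2} over per-SNP Wald
#' ratios \eqn{\beta_j} with IVW weights \eqn{w_j = \gamma_j^2/se_{\Gamma_j}^2};
#' under homogeneity Q is chi-square with J - 1 degrees of freedom.
#'
#' @inheritParams ivw
#' @return A `heterogeneity_result` list: `Q`, `df`, `pval`, `phi` (the
#'   dispersion Q/df) and per-SNP `contributions` (which sum to Q exactly).
#' @export
cochran_q <- function(pairs) {
  rs <- .ratio_stats(pairs)
  J <- length(rs$b)
  if (J < 2L) {
    stop_medimr("cochran_q needs at least 2 instruments",
                "medimr_insufficient_instruments_error")
  }
  qs <- .cochran_q_stat(rs)
  structure(list(Q = qs$Q, df = J - 1L,
                 pval = stats::pchisq(qs$Q, df = J - 1, lower.tail = FALSE),
                 phi = qs$Q / (J - 1),
                 contributions = qs$contributions),
            class = "heterogeneity_result")
}

#' @export
print.heterogeneity_result <- function(x, ...) {
  cat(sprintf("Cochran's Q = %.4g on %d df (p = %.3g, dispersion %.3g)\n",
              x$Q, x$df, x$pval, x$phi))
  invisible(x)
}

# Leave-one-out fixed-effects IVW slopes for all SNPs at once.
# b, w: ratio estimates and IVW weights. Returns vector of slopes beta_{-j}.
.loo_slopes <- function(b, w) {
  (sum(w * b) - w * b) / (sum(w) - w)
}

#' MR-PRESSO global and outlier tests
#'
#' Simulation-based pleiotropy residual sum and outlier test. For each SNP
#' the leave-one-out IVW slope \eqn{\hat\beta_{-j}} gives a predicted
#' outcome effect; the observed statistic is the weighted residual sum of
#' squares \eqn{RSS = \sum_j (\Gamma_j - \hat\beta_{-j}\gamma_j)^2 /
#' se_{\Gamma_j}^2}. Its null distribution is built by redrawing, `n_sim`
#' times, \eqn{\Gamma_j^* \sim N(\hat\beta_{-j}\gamma_j, se_{\Gamma_j})} and
#' \eqn{\gamma_j^* \sim N(\gamma_j, se_{\gamma_j})} and recomputing the
#' statistic. Empirical p-values use the add-one estimator
#' `(1 + #[sim >= obs]) / (n_sim + 1)`, so the smallest attainable p is
#' `1/(n_sim+1)`. Per-SNP outlier p-values are computed analogously from
#' each SNP's residual contribution and Bonferroni-adjusted; SNPs with
#' adjusted p below `outlier_alpha` are flagged and removed once (no
#' iteration), after which a multiplicative-random-effects IVW estimate on
#' the remaining SNPs is returned. The distortion test of the original
#' method is not implemented. Pairs are ordered canonically by SNP id
#' before simulation, so results do not depend on input order.
#'
#' @inheritParams ivw
#' @param n_sim Number of null simulations (values below 100 warn).
#' @param seed Mandatory integer seed, recorded in the result.
#' @param outlier_alpha Significance level applied to Bonferroni-adjusted
#'   per-SNP outlier p-values.
#' @return A `presso_result` list: `rss_obs`, `global_pval`,
#'   `outlier_pvals` (named, Bonferroni-adjusted), `outlier_ids`,
#'   `ivw_corrected` (`mr_estimate` on non-outliers, or `NULL` when fewer
#'   than two remain), `n_sim`, `seed`.
#' @export
mr_presso <- function(pairs, n_sim = 1000, seed, outlier_alpha = 0.05) {
  if (missing(seed)) stop_medimr("mr_presso requires an explicit seed",
                                 "medimr_config_error")
  p <- kept_pairs(pairs)
  J <- nrow(p)
  if (J < 4L) {
    stop_medimr(sprintf("mr_presso needs at least 4 instruments, got %d", J),
                "medimr_insufficient_instruments_error")
  }
  if (n_sim < 100) warning("mr_presso: n_sim < 100 gives a coarse null distribution")
  p <- p[order(p$snp_id), , drop = FALSE]

  gam <- p$beta_exp; Gam <- p$beta_out
  se_g <- p$se_exp; se_G <- p$se_out
  w <- gam^2 / se_G^2
  b <- Gam / gam
  loo <- .loo_slopes(b, w)
  d_obs <- (Gam - loo * gam)^2 / se_G^2
  rss_obs <- sum(d_obs)

  sims <- withr_seed(seed, {
    Gs <- matrix(stats::rnorm(n_sim * J, mean = rep(loo * gam, each = n_sim),
                              sd = rep(se_G, each = n_sim)), nrow = n_sim)
    gs <- matrix(stats::rnorm(n_sim * J, mean = rep(gam, each = n_sim),
                              sd = rep(se_g, each = n_sim)), nrow = n_sim)
    list(Gs = Gs, gs = gs)
  })
  ws <- sims$gs^2 / matrix(se_G^2, n_sim, J, byrow = TRUE)
  bs <- sims$Gs / sims$gs
  tot_wb <- rowSums(ws * bs); tot_w <- rowSums(ws)
  loo_s <- (tot_wb - ws * bs) / (tot_w - ws)
  d_sim <- (sims$Gs - loo_s * sims$gs)^2 / matrix(se_G^2, n_sim, J, byrow = TRUE)
  rss_sim <- rowSums(d_sim)

  global_pval <- (1 + sum(rss_sim >= rss_obs)) / (n_sim + 1)
  raw_p <- (1 + colSums(d_sim >= matrix(d_obs, n_sim, J, byrow = TRUE))) /
    (n_sim + 1)
  adj_p <- pmin(1, raw_p * J)
  names(adj_p) <- p$snp_id
  outlier_ids <- p$snp_id[adj_p < outlier_alpha]

  remaining <- p[!(p$snp_id %in% outlier_ids), , drop = FALSE]
  ivw_corrected <- if (nrow(remaining) >= 2L) ivw(remaining) else NULL

  structure(list(rss_obs = rss_obs, global_pval = global_pval,
                 outlier_pvals = adj_p, outlier_ids = outlier_ids,
                 ivw_corrected = ivw_corrected,
                 n_sim = as.integer(n_sim), seed = as.integer(seed)),
            class = "presso_result")
}

#' @export
print.presso_result <- function(x, ...) {
  cat(sprintf("MR-PRESSO: RSS = %.4g, global p = %.4g (%d simulations, seed %d)\n",
              x$rss_obs, x$global_pval, x$n_sim, x$seed))
  if (length(x$outlier_ids) > 0L) {
    cat("outliers:", paste(x$outlier_ids, collapse = ", "), "\n")
  } else {
    cat("no outliers flagged\n")
  }
  invisible(x)
}

#' Leave-one-out analysis
#'
#' Recomputes the multiplicative-random-effects IVW estimate J times, each
#' omitting one SNP, alongside the all-SNP estimate (row `"(all)"`).
#'
#' @inheritParams ivw
#' @return Data.frame with columns `snp_id` (the omitted SNP), `beta`,
#'   `se`, `ci_low`, `ci_high`, `pval`, `n_snp`.
#' @export
leave_one_out <- function(pairs, level = 0.95) {
  p <- kept_pairs(pairs)
  J <- nrow(p)
  if (J < 3L) {
    stop_medimr(sprintf("leave_one_out needs at least 3 instruments, got %d", J),
                "medimr_insufficient_instruments_error")
  }
  one <- function(drop_id, sub) {
    est <- ivw(sub, model = "multiplicative_random", level = level)
    data.frame(snp_id = drop_id, beta = est$beta, se = est$se,
               ci_low = est$ci_low, ci_high = est$ci_high,
               pval = est$pval, n_snp = est$n_snp, stringsAsFactors = FALSE)
  }
  rows <- lapply(seq_len(J), function(j) one(p$snp_id[j], p[-j, , drop = FALSE]))
  out <- rbind(do.call(rbind, rows), one("(all)", p))
  rownames(out) <- NULL
  out
}

#' One-row sensitivity report for an analysis
#'
#' Combines Cochran's Q, the MR-Egger intercept test and the MR-PRESSO
#' global test into the per-analysis diagnostic row used by the pipeline.
#'
#' @inheritParams mr_presso
#' @param presso_n_sim Simulations for the MR-PRESSO null distribution.
#' @return One-row data.frame: `Q`, `Q_df`, `Q_pval`, `egger_intercept`,
#'   `egger_intercept_pval`, `presso_global_pval`, `n_outliers`, `seed`.
#'   Diagnostics whose instrument-count preconditions are not met are NA.
#' @export
sensitivity_report <- function(pairs, seed, presso_n_sim = 1000,
                               outlier_alpha = 0.05) {
  p <- kept_pairs(pairs)
  J <- nrow(p)
  q <- if (J >= 2L) cochran_q(p) else NULL
  eg <- if (J >= 3L) mr_egger(p) else NULL
  pr <- if (J >= 4L) mr_presso(p, n_sim = presso_n_sim, seed = seed,
                               outlier_alpha = outlier_alpha) else NULL
  data.frame(
    Q = if (is.null(q)) NA_real_ else q$Q,
    Q_df = if (is.null(q)) NA_integer_ else q$df,
    Q_pval = if (is.null(q)) NA_real_ else q$pval,
    egger_intercept = if (is.null(eg)) NA_real_ else eg$intercept$beta,
    egger_intercept_pval = if (is.null(eg)) NA_real_ else eg$intercept$pval,
    presso_global_pval = if (is.null(pr)) NA_real_ else pr$global_pval,
    n_outliers = if (is.null(pr)) NA_integer_ else length(pr$outlier_ids),
    seed = as.integer(seed),
    stringsAsFactors = FALSE
  )
}
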