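# Allele harmonization of exposure/outcome summary statistics onto the
# exposure's effect-allele frame, and odds-ratio <-> log-odds conversion.

#' Harmonize exposure and outcome summary statistics
#'
#' Aligns the outcome associations of shared SNPs onto the exposure's
#' effect-allele frame. The exposure beta is never sign-flipped. For each
#' shared SNP:
#'
#' * same allele pair, same orientation: kept as is;
#' * same pair with effect/other swapped: outcome beta negated and its
#'   frequency complemented (`flipped`);
#' * pair matching only after strand complement (A<->T, C<->G): complemented,
#'   then the two cases above;
#' * palindromic SNP (A/T or C/G): resolved per `palindrome_policy`;
#' * irreconcilable alleles: `dropped_mismatch`.
#'
#' Palindromic policies: `"drop_all"` drops every palindromic SNP.
#' `"drop_ambiguous"` (default) drops palindromic SNPs whose exposure or
#' outcome effect-allele frequency lies in the ambiguous window
#' `[freq_threshold, 1 - freq_threshold]` or is missing, and infers the
#' strand from allele frequency otherwise (frequencies on opposite sides of
#' 0.5 indicate opposite strands). `"infer_by_freq"` infers from frequency
#' whenever both frequencies are present and differ from 0.5, ignoring the
#' ambiguity window.
#'
#' @param exposure,outcome `sumstats` objects (see [sumstats()]).
#' @param palindrome_policy One of `"drop_ambiguous"`, `"drop_all"`,
#'   `"infer_by_freq"`.
#' @param freq_threshold Lower edge of the ambiguous frequency window;
#'   default 0.42 gives the conventional window \[0.42, 0.58\].
#' @return A `harmonized_pairs` data.frame with columns `snp_id`,
#'   `beta_exp`, `se_exp`, `beta_out`, `se_out`, `eaf` (exposure frame),
#'   `f_stat` (per-instrument F, \eqn{(\gamma_j/se_{\gamma_j})^2}, reported
#'   for information) and `action`. Pairs whose action starts with
#'   `dropped_` are excluded by all downstream estimators. The full
#'   per-SNP action table is attached as attribute `report`.
#' @export
harmonize <- function(exposure, outcome,
                      palindrome_policy = c("drop_ambiguous", "drop_all",
                                            "infer_by_freq"),
                      freq_threshold = 0.42) {
  palindrome_policy <- match.arg(palindrome_policy)
  stopifnot(inherits(exposure, "sumstats"), inherits(outcome, "sumstats"),
            is.numeric(freq_threshold), freq_threshold > 0, freq_threshold <= 0.5)
  shared <- intersect(exposure$snp_id, outcome$snp_id)
  if (length(shared) == 0L) {
    stop_medimr("no shared SNPs between exposure and outcome",
                "medimr_empty_overlap_error")
  }
  e <- as.data.frame(exposure)[match(shared, exposure$snp_id), , drop = FALSE]
  o <- as.data.frame(outcome)[match(shared, outcome$snp_id), , drop = FALSE]

  ea <- e$effect_allele; oa <- e$other_allele
  pal <- is_palindromic(ea, oa)
  oea <- o$effect_allele; ooa <- o$other_allele

  same    <- oea == ea & ooa == oa
  swapped <- oea == oa & ooa == ea
  csame   <- complement_allele(oea) == ea & complement_allele(ooa) == oa
  cswap   <- complement_allele(oea) == oa & complement_allele(ooa) == ea

  beta_out <- o$beta
  eaf_out <- o$eaf
  action <- rep("dropped_mismatch", length(shared))

  # Non-palindromic pairs resolve uniquely; for palindromic pairs the
  # complement coincides with the swap, so only the literal orientation is
  # meaningful and the strand must come from frequency (below).
  keep_idx <- (!pal & (same | csame)) | (pal & same)
  flip_idx <- (!pal & (swapped | cswap)) | (pal & !same & swapped)
  action[keep_idx] <- "kept_as_is"
  action[flip_idx] <- "flipped"
  beta_out[flip_idx] <- -beta_out[flip_idx]
  eaf_out[flip_idx] <- 1 - eaf_out[flip_idx]

  if (any(pal & action != "dropped_mismatch")) {
    idx <- which(pal & action != "dropped_mismatch")
    if (palindrome_policy == "drop_all") {
      action[idx] <- "dropped_palindromic"
    } else {
      amb_win <- function(f) !is.na(f) & f >= freq_threshold & f <= 1 - freq_threshold
      for (i in idx) {
        fe <- e$eaf[i]; fo <- eaf_out[i]  # outcome eaf already letter-aligned
        unresolvable <- is.na(fe) || is.na(fo) || fe == 0.5 || fo == 0.5
        ambiguous <- unresolvable ||
          (palindrome_policy == "drop_ambiguous" && (amb_win(fe) || amb_win(fo)))
        if (ambiguous) {
          action[i] <- "dropped_palindromic"
        } else if ((fe < 0.5) != (fo < 0.5)) {
          # Opposite sides of 0.5: outcome is on the other strand, so the
          # letter-level alignment chose the wrong orientation; undo it.
          beta_out[i] <- -beta_out[i]
          eaf_out[i] <- 1 - eaf_out[i]
          action[i] <- if (action[i] == "flipped") "kept_as_is" else "flipped"
        }
      }
    }
  }

  res <- data.frame(
    snp_id = shared,
    beta_exp = e$beta, se_exp = e$se,
    beta_out = beta_out, se_out = o$se,
    eaf = e$eaf,
    f_stat = (e$beta / e$se)^2,
    action = action,
    stringsAsFactors = FALSE
  )
  rownames(res) <- NULL
  structure(res,
            report = res[c("snp_id", "action")],
            exposure_id = attr(exposure, "trait_id"),
            outcome_id = attr(outcome, "trait_id"),
            class = c("harmonized_pairs", "data.frame"))
}

# Pairs retained for analysis (dropped_* excluded).
kept_pairs <- function(pairs) {
  stopifnot(is.data.frame(pairs))
  out <- pairs[!startsWith(pairs$action %||% "kept_as_is", "dropped"), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Convert a reported odds ratio and confidence interval to the log scale
#'
#' Inverts the usual reporting convention `OR [low-high]` back to a log-odds
#' point estimate and standard error: `beta = log(or_point)`,
#' `se = (log(ci_high) - log(ci_low)) / (2 z*)` with `z*` the exact normal
#' quantile for the coverage level.
#'
#' @param or_point,ci_low,ci_high Odds-ratio point estimate and interval
#'   bounds; all must be positive with `ci_low <= or_point <= ci_high`.
#' @param level Interval coverage (default 0.95).
#' @return List with elements `beta` and `se`.
#' @export
#' @examples
#' or_ci_to_logscale(0.888, 0.824, 0.958)
or_ci_to_logscale <- function(or_point, ci_low, ci_high, level = 0.95) {
  if (any(!is.finite(c(or_point, ci_low, ci_high))) ||
      any(c(or_point, ci_low, ci_high) <= 0)) {
    stop_medimr("odds ratios and CI bounds must be positive", "medimr_domain_error")
  }
  if (ci_low > or_point || or_point > ci_high) {
    stop_medimr("require ci_low <= or_point <= ci_high", "medimr_domain_error")
  }
  list(beta = log(or_point),
       se = (log(ci_high) - log(ci_low)) / (2 * z_level(level)))
}
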