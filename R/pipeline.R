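# Orchestration of the study design at desk scale: exposure screen against
# one outcome, two-step mediator screen, mediation estimation, validation
# against a second outcome dataset; TSV outputs plus a run manifest.

#' Configuration for a full analysis run
#'
#' Bundles the selection thresholds (a relaxed discovery threshold of
#' `p < 5e-6` for screening many candidate exposures, `p < 5e-8`
#' elsewhere), the harmonization policy, significance levels, simulation
#' sizes for the stochastic diagnostics, and the master seed from which
#' every stage-level seed is derived deterministically.
#'
#' @param seed Master integer seed; recorded in all outputs.
#' @param discovery [selection_params()] for the exposure discovery screen.
#' @param standard [selection_params()] for every other instrument set.
#' @param palindrome_policy,freq_threshold Passed to [harmonize()].
#' @param alpha Per-test significance level (consistency filter).
#' @param fdr_threshold FDR level used when flagging screen hits.
#' @param n_boot Bootstrap resamples for the weighted median.
#' @param presso_n_sim Simulations for MR-PRESSO.
#' @param min_instruments Minimum surviving instruments before an exposure
#'   or mediator is skipped (with a logged reason) rather than analysed.
#' @param out_dir Optional directory; when set, every stage writes its TSV
#'   outputs and a YAML run manifest there.
#' @return An `analysis_config` list.
#' @export
analysis_config <- function(seed,
                            discovery = selection_params(p_threshold = 5e-6),
                            standard = selection_params(p_threshold = 5e-8),
                            palindrome_policy = "drop_ambiguous",
                            freq_threshold = 0.42,
                            alpha = 0.05, fdr_threshold = 0.05,
                            n_boot = 1000, presso_n_sim = 1000,
                            min_instruments = 2L, out_dir = NULL) {
  stopifnot(is.numeric(seed), length(seed) == 1L,
            inherits(discovery, "selection_params"),
            inherits(standard, "selection_params"))
  structure(list(seed = as.integer(seed), discovery = discovery,
                 standard = standard,
                 palindrome_policy = palindrome_policy,
                 freq_threshold = freq_threshold,
                 alpha = alpha, fdr_threshold = fdr_threshold,
                 n_boot = n_boot, presso_n_sim = presso_n_sim,
                 min_instruments = as.integer(min_instruments),
                 out_dir = out_dir),
            class = "analysis_config")
}

.harmonize_cfg <- function(config, instruments, outcome) {
  harmonize(instruments, outcome,
            palindrome_policy = config$palindrome_policy,
            freq_threshold = config$freq_threshold)
}

# All-method estimate rows + sensitivity row for one harmonized pair set.
.mr_all_methods <- function(pairs, config, seed) {
  kept <- kept_pairs(pairs)
  J <- nrow(kept)
  rows <- list(ivw(kept, "multiplicative_random"), ivw(kept, "fixed"))
  if (J >= 3L) {
    eg <- mr_egger(kept)
    rows <- c(rows, list(eg$slope, eg$intercept,
                         weighted_median(kept, n_boot = config$n_boot,
                                         seed = seed)))
  }
  est <- do.call(rbind, lapply(rows, function(r) {
    r$seed <- if (is.null(r$seed)) NA_integer_ else r$seed
    as.data.frame(r)
  }))
  sens <- sensitivity_report(kept, seed = seed,
                             presso_n_sim = config$presso_n_sim)
  list(estimates = est, sensitivity = sens)
}

.write_stage <- function(config, name, tables) {
  if (is.null(config$out_dir)) return(invisible(NULL))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(tables)) {
    utils::write.table(tables[[nm]],
                       file.path(config$out_dir, paste0(name, "_", nm, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  manifest <- list(stage = name, seed = config$seed,
                   package_version = as.character(utils::packageVersion("medimr")),
                   thresholds = list(
                     discovery_p = config$discovery$p_threshold,
                     standard_p = config$standard$p_threshold,
                     r2 = config$standard$r2_threshold,
                     window_kb = config$standard$window_kb,
                     maf_min = config$standard$maf_min),
                   alpha = config$alpha, fdr_threshold = config$fdr_threshold,
                   palindrome_policy = config$palindrome_policy)
  yaml::write_yaml(manifest, file.path(config$out_dir,
                                       paste0(name, "_manifest.yaml")))
  invisible(NULL)
}

#' Screen candidate exposures against an outcome
#'
#' For each exposure: instrument selection at the discovery thresholds,
#' harmonization with the outcome, the full estimator battery
#' (multiplicative-random and fixed IVW, MR-Egger, weighted median) and the
#' sensitivity report. BH-FDR is applied across the exposure family to the
#' primary (multiplicative-random IVW) p-values, and the family size is
#' recorded alongside each q-value. Exposures with too few surviving
#' instruments are skipped with a machine-readable reason, not failed.
#'
#' @param config An [analysis_config()].
#' @param exposures Named list of `sumstats` tables.
#' @param outcome A `sumstats` table.
#' @param ld An [ld_matrix()] covering all exposure SNPs, or a named list
#'   of matrices parallel to `exposures`.
#' @return List: `results` (one row per exposure and method, with `qval`
#'   and `fdr_family_size` on the primary rows), `sensitivity` (one row per
#'   exposure), `skipped` (exposure, reason).
#' @export
run_exposure_screen <- function(config, exposures, outcome, ld) {
  stopifnot(inherits(config, "analysis_config"), is.list(exposures),
            length(exposures) > 0L, !is.null(names(exposures)))
  results <- list(); sens <- list(); skipped <- list()
  for (i in seq_along(exposures)) {
    name <- names(exposures)[i]
    ld_i <- if (inherits(ld, "ld_matrix")) ld else ld[[name]]
    instr <- select_instruments(exposures[[i]], ld_i, config$discovery)
    if (nrow(instr) < config$min_instruments) {
      skipped[[name]] <- sprintf("only %d instrument(s) after selection", nrow(instr))
      next
    }
    pairs <- tryCatch(.harmonize_cfg(config, instr, outcome),
                      medimr_empty_overlap_error = function(e) NULL)
    kept <- if (is.null(pairs)) pairs else kept_pairs(pairs)
    if (is.null(kept) || nrow(kept) < config$min_instruments) {
      skipped[[name]] <- "too few instruments after harmonization"
      next
    }
    res <- .mr_all_methods(kept, config, derive_seed(config$seed, i))
    res$estimates$exposure <- name
    res$sensitivity$exposure <- name
    results[[name]] <- res$estimates
    sens[[name]] <- res$sensitivity
  }
  results <- if (length(results)) do.call(rbind, c(results, make.row.names = FALSE)) else NULL
  if (!is.null(results)) {
    primary <- results$method == "ivw_mre"
    results$qval <- NA_real_
    results$fdr_family_size <- NA_integer_
    results$qval[primary] <- bh_fdr(results$pval[primary])
    results$fdr_family_size[primary] <- sum(primary)
  }
  sens <- if (length(sens)) do.call(rbind, c(sens, make.row.names = FALSE)) else NULL
  skipped <- data.frame(exposure = names(skipped),
                        reason = unlist(skipped) %||% character(0),
                        stringsAsFactors = FALSE, row.names = NULL)
  out <- list(results = results, sensitivity = sens, skipped = skipped)
  .write_stage(config, "screen",
               Filter(Negate(is.null), out))
  out
}

# Univariable MR for one exposure/outcome pair at the standard thresholds.
.mr_step <- function(config, exposure_tab, outcome_tab, ld, seed,
                     params = NULL) {
  instr <- select_instruments(exposure_tab, ld, params %||% config$standard)
  if (nrow(instr) < config$min_instruments) {
    return(list(estimate = NULL,
                reason = sprintf("only %d instrument(s) after selection",
                                 nrow(instr))))
  }
  pairs <- .harmonize_cfg(config, instr, outcome_tab)
  kept <- kept_pairs(pairs)
  if (nrow(kept) < config$min_instruments) {
    return(list(estimate = NULL, reason = "too few instruments after harmonization"))
  }
  list(estimate = ivw(kept, "multiplicative_random"), pairs = kept, reason = NULL)
}

#' Two-step mediation screen
#'
#' For an exposure that passed the screen, estimates for each candidate
#' mediator: step 1, the exposure-mediator effect from the exposure's
#' instruments; step 2, the mediator-outcome effect from the mediator's own
#' instruments (univariable, not multivariable-adjusted); and combines them
#' with the total exposure-outcome effect into [two_step_mediation()]
#' rows. BH-FDR q-values are appended over the mediator family, and the
#' direction-consistency + significance filter gives the retained set.
#'
#' @param config An [analysis_config()].
#' @param exposure `sumstats` for the exposure.
#' @param mediators Named list of `sumstats` candidate mediators.
#' @param outcome `sumstats` for the outcome.
#' @param ld [ld_matrix()] covering exposure and mediator SNPs, or a named
#'   list with an entry per mediator plus `"exposure"`.
#' @return List: `all` (one mediation row per analysable mediator, with
#'   `qval`, `fdr_family_size`), `retained` (after [consistency_filter()]),
#'   `tau` (the total-effect `mr_estimate`), `skipped`.
#' @export
run_mediation_screen <- function(config, exposure, mediators, outcome, ld) {
  stopifnot(inherits(config, "analysis_config"), is.list(mediators),
            !is.null(names(mediators)))
  ld_for <- function(name) if (inherits(ld, "ld_matrix")) ld else ld[[name]]
  tau_fit <- .mr_step(config, exposure, outcome, ld_for("exposure"),
                      derive_seed(config$seed, 101L))
  if (is.null(tau_fit$estimate)) {
    stop_medimr(paste0("total-effect estimation failed: ", tau_fit$reason),
                "medimr_insufficient_instruments_error")
  }
  rows <- list(); skipped <- list()
  for (i in seq_along(mediators)) {
    name <- names(mediators)[i]
    step1 <- .mr_step(config, exposure, mediators[[i]], ld_for("exposure"),
                      derive_seed(config$seed, 200L + i))
    if (is.null(step1$estimate)) {
      skipped[[name]] <- paste0("step 1: ", step1$reason); next
    }
    step2 <- .mr_step(config, mediators[[i]], outcome, ld_for(name),
                      derive_seed(config$seed, 300L + i))
    if (is.null(step2$estimate)) {
      skipped[[name]] <- paste0("step 2: ", step2$reason); next
    }
    med <- two_step_mediation(step1$estimate, step2$estimate, tau_fit$estimate)
    med$mediator <- name
    rows[[name]] <- as.data.frame(med)
  }
  all <- if (length(rows)) do.call(rbind, c(rows, make.row.names = FALSE)) else NULL
  retained <- NULL
  if (!is.null(all)) {
    all$qval <- bh_fdr(all$pval)
    all$fdr_family_size <- nrow(all)
    retained <- consistency_filter(all, alpha = config$alpha)
  }
  skipped <- data.frame(mediator = names(skipped),
                        reason = unlist(skipped) %||% character(0),
                        stringsAsFactors = FALSE, row.names = NULL)
  out <- list(all = all, retained = retained, tau = tau_fit$estimate,
              skipped = skipped)
  .write_stage(config, "mediation",
               Filter(function(x) is.data.frame(x) && nrow(x) > 0,
                      list(all = all, retained = retained, skipped = skipped)))
  out
}

#' Validate a mediation result against a second outcome dataset
#'
#' Re-estimates the full two-step decomposition with an independent outcome
#' GWAS and, when the discovery-stage result is supplied, returns a
#' side-by-side comparison of the mediated proportions with their CIs.
#'
#' @param config An [analysis_config()].
#' @param exposure,mediator `sumstats` tables.
#' @param outcome2 `sumstats` for the validation outcome.
#' @param ld As in [run_mediation_screen()].
#' @param discovery Optional `mediation_result` row from the discovery run.
#' @return List: `result` (the validation `mediation_result`) and
#'   `comparison` (NULL unless `discovery` given: stage, proportion,
#'   CI bounds, p).
#' @export
run_validation <- function(config, exposure, mediator, outcome2, ld,
                           discovery = NULL) {
  screen <- run_mediation_screen(config, exposure,
                                 mediators = list(validation = mediator),
                                 outcome = outcome2, ld = ld)
  if (is.null(screen$all)) {
    stop_medimr(paste0("validation failed: ",
                       paste(screen$skipped$reason, collapse = "; ")),
                "medimr_insufficient_instruments_error")
  }
  result <- screen$all
  comparison <- NULL
  if (!is.null(discovery)) {
    comparison <- data.frame(
      stage = c("discovery", "validation"),
      proportion = c(discovery$proportion, result$proportion),
      ci_low_prop = c(discovery$ci_low_prop, result$ci_low_prop),
      ci_high_prop = c(discovery$ci_high_prop, result$ci_high_prop),
      pval = c(discovery$pval, result$pval),
      stringsAsFactors = FALSE)
    .write_stage(config, "validation", list(comparison = comparison))
  }
  list(result = result, comparison = comparison)
}
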