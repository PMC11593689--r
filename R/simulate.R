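# Synthetic three-trait GWAS summary statistics with known causal
# structure: exposure X, mediator M (influenced by X and by its own
# instruments), outcome Y (influenced by X directly and via M), plus
# optional horizontal pleiotropy, LD blocks, and allele-encoding hazards.

#' Configuration for the three-trait summary-statistics generator
#'
#' The generative model, all on a per-allele scale (log-odds for the binary
#' outcome): `J` SNPs instrument the exposure X with marginal effects
#' \eqn{\gamma_j} scaled so the instruments explain `h2_x` of the variance
#' of X; `J_m` further SNPs act on the mediator M directly with effects
#' scaled to `h2_m` (these are M's own instruments, as cis-pQTLs are for a
#' protein — without them the mediator-outcome step of two-step mediation
#' is not identifiable). True marginal effects are then: on M,
#' \eqn{\alpha\gamma_j} (X SNPs) and \eqn{\delta_k} (M SNPs); on Y,
#' \eqn{(\theta + \alpha b)\gamma_j + p_j} (X SNPs, with pleiotropic direct
#' effects \eqn{p_j}) and \eqn{b\,\delta_k} (M SNPs). Observed effects add
#' sampling noise with SE \eqn{1/\sqrt{2 f (1-f) n}} for allele frequency
#' `f` and trait sample size `n`. The implied total effect is
#' \eqn{\tau = \theta + \alpha b} and the true proportion mediated
#' \eqn{\alpha b / \tau}.
#'
#' Default sample sizes mirror the scale of contemporary biobank GWAS for
#' the exposure and outcome (~4.6e5 and ~4.8e5) and of large proteogenomic
#' cohorts for the mediator (~3.6e4). Per-SNP contributions to `h2_x`/`h2_m`
#' are drawn uniformly within a 3-fold range, giving the comparable
#' instrument strengths typical of clumped genome-wide-significant hits.
#'
#' @param J Number of exposure instruments.
#' @param J_m Number of mediator-specific instruments.
#' @param maf_range Allele-frequency range (within (0.01, 0.5)).
#' @param h2_x,h2_m Variance explained in X by its `J` SNPs and in M by its
#'   `J_m` SNPs.
#' @param alpha True effect of X on M.
#' @param b_true True effect of M on Y.
#' @param theta_direct True direct effect of X on Y.
#' @param pleio_mean,pleio_sd Mean and SD of the per-SNP direct (horizontal
#'   pleiotropic) effect of X SNPs on Y, defined relative to the
#'   exposure-increasing allele; `pleio_mean = 0` gives balanced, non-zero
#'   directional pleiotropy.
#' @param pleio_inside If `FALSE`, pleiotropic effects are correlated with
#'   instrument strength (violating the InSIDE assumption).
#' @param n_x,n_m,n_y GWAS sample sizes per trait (all >= 100).
#' @param ld_block_size SNPs per LD block (1 = independent SNPs).
#' @param ld_rho Within-block correlation of adjacent SNPs (r, not r^2);
#'   correlation decays as `ld_rho^|i-j|` inside a block.
#' @param harmonization_noise Fraction of SNPs emitted with corrupted
#'   allele encodings (swaps, strand flips, palindromic conversions applied
#'   consistently across the three tables; see [corrupt_encoding()]).
#' @param seed Integer seed.
#' @return A `sim_config` list.
#' @export
sim_config <- function(J = 100, J_m = 30, maf_range = c(0.05, 0.5),
                       h2_x = 0.05, h2_m = 0.15,
                       alpha = 0.11, b_true = 0.11, theta_direct = 0.088,
                       pleio_mean = 0, pleio_sd = 0, pleio_inside = TRUE,
                       n_x = 461384, n_m = 35559, n_y = 484598,
                       ld_block_size = 1, ld_rho = 0,
                       harmonization_noise = 0, seed = 1) {
  stopifnot(J >= 1, J_m >= 0, length(maf_range) == 2L,
            maf_range[1] > 0.01, maf_range[2] <= 0.5,
            maf_range[1] <= maf_range[2],
            n_x >= 100, n_m >= 100, n_y >= 100,
            ld_block_size >= 1, ld_rho >= 0, ld_rho < 1,
            harmonization_noise >= 0, harmonization_noise <= 1)
  if (h2_x <= 0 || h2_x > 1 || h2_m < 0 || h2_m > 1) {
    stop_medimr("heritabilities must lie in (0, 1]", "medimr_domain_error")
  }
  structure(list(J = as.integer(J), J_m = as.integer(J_m),
                 maf_range = maf_range, h2_x = h2_x, h2_m = h2_m,
                 alpha = alpha, b_true = b_true, theta_direct = theta_direct,
                 pleio_mean = pleio_mean, pleio_sd = pleio_sd,
                 pleio_inside = pleio_inside,
                 n_x = n_x, n_m = n_m, n_y = n_y,
                 ld_block_size = as.integer(ld_block_size), ld_rho = ld_rho,
                 harmonization_noise = harmonization_noise,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# Effect sizes with per-SNP variance shares u ~ U(0.5, 1.5), scaled so
# sum(2 f (1-f) beta^2) = h2, with random signs.
.scaled_effects <- function(n, maf, h2) {
  if (n == 0L) return(numeric(0))
  u <- stats::runif(n, 0.5, 1.5)
  v <- 2 * maf * (1 - maf)
  sgn <- sample(c(-1, 1), n, replace = TRUE)
  sgn * sqrt(h2 * (u / sum(u)) / v)
}

# Block-correlated standard-normal noise: correlation rho^|i-j| within
# consecutive blocks of the given size.
.block_noise <- function(n, block_size, rho) {
  z <- stats::rnorm(n)
  if (block_size <= 1L || rho == 0 || n < 2L) return(z)
  blocks <- split(seq_len(n), ceiling(seq_len(n) / block_size))
  for (idx in blocks) {
    k <- length(idx)
    if (k < 2L) next
    R <- rho^abs(outer(seq_len(k), seq_len(k), "-"))
    z[idx] <- as.vector(t(chol(R)) %*% z[idx])
  }
  z
}

# Non-palindromic allele pairs sampled per SNP.
.draw_alleles <- function(n) {
  pairs <- rbind(c("A", "G"), c("A", "C"), c("G", "T"), c("C", "T"),
                 c("G", "A"), c("C", "A"), c("T", "G"), c("T", "C"))
  pick <- sample(nrow(pairs), n, replace = TRUE)
  list(ea = pairs[pick, 1L], oa = pairs[pick, 2L])
}

#' Simulate three-trait GWAS summary statistics with known truth
#'
#' Generates exposure, mediator and outcome summary-statistics tables (see
#' [sim_config()] for the model), an LD matrix with block structure, and a
#' truth record. Summary statistics are drawn directly from the asymptotic
#' sampling distribution of marginal GWAS estimates (no individual-level
#' genotypes); LD enters through the emitted r-squared matrix and through
#' correlated sampling noise within blocks. Exposure, mediator and outcome
#' samples are non-overlapping (independent noise), matching the two-sample
#' independence assumed by the delta method downstream.
#'
#' X SNPs are placed on chromosome 1 and M SNPs on chromosome 2, with LD
#' blocks 20,000 kb apart (beyond the default clumping window) and 1 kb
#' between SNPs within a block.
#'
#' @param config A [sim_config()] list.
#' @return List with `sumstats` elements `exposure`, `mediator`, `outcome`,
#'   an `ld` matrix ([ld_matrix()]), and `truth`: a list carrying the
#'   per-SNP true effects (`gamma`, `delta`, `pleio`), `maf`,
#'   `tau_true = theta_direct + alpha * b_true`, `proportion_true =
#'   alpha * b_true / tau_true` (NA when `tau_true` is 0), and the config.
#' @export
simulate_sumstats <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  withr_seed(cfg$seed, {
    Jx <- cfg$J; Jm <- cfg$J_m; n <- Jx + Jm
    maf <- stats::runif(n, cfg$maf_range[1], cfg$maf_range[2])
    gamma <- .scaled_effects(Jx, maf[seq_len(Jx)], cfg$h2_x)
    delta <- if (Jm > 0L) .scaled_effects(Jm, maf[Jx + seq_len(Jm)], cfg$h2_m) else numeric(0)

    pleio <- if (cfg$pleio_sd > 0 || cfg$pleio_mean != 0) {
      if (cfg$pleio_inside) {
        stats::rnorm(Jx, cfg$pleio_mean, cfg$pleio_sd)
      } else {
        # InSIDE violation: pleiotropy tracks instrument strength.
        gs <- abs(gamma); gs <- (gs - mean(gs)) / max(stats::sd(gs), 1e-12)
        cfg$pleio_mean + cfg$pleio_sd * (0.7 * gs + sqrt(1 - 0.49) * stats::rnorm(Jx))
      }
    } else rep(0, Jx)

    tau_true <- cfg$theta_direct + cfg$alpha * cfg$b_true
    truth_x <- c(gamma, rep(0, Jm))
    truth_m <- c(cfg$alpha * gamma, delta)
    # Pleiotropic direct effects act on the exposure-increasing allele, so
    # a non-zero pleio_mean shifts outcome effects in a consistent
    # direction relative to the instrument orientation (directional
    # pleiotropy in the usual sense).
    truth_y <- c(tau_true * gamma + sign(gamma) * pleio, cfg$b_true * delta)

    base_se <- 1 / sqrt(2 * maf * (1 - maf))
    se_x <- base_se / sqrt(cfg$n_x)
    se_m <- base_se / sqrt(cfg$n_m)
    se_y <- base_se / sqrt(cfg$n_y)

    noise <- function() {
      zx <- .block_noise(Jx, cfg$ld_block_size, cfg$ld_rho)
      zm <- if (Jm > 0L) .block_noise(Jm, cfg$ld_block_size, cfg$ld_rho) else numeric(0)
      c(zx, zm)
    }
    beta_x <- truth_x + noise() * se_x
    beta_m <- truth_m + noise() * se_m
    beta_y <- truth_y + noise() * se_y

    eaf <- ifelse(stats::runif(n) < 0.5, maf, 1 - maf)
    al <- .draw_alleles(n)

    block_pos <- function(k) {
      if (k == 0L) return(integer(0))
      block <- ceiling(seq_len(k) / cfg$ld_block_size)
      within <- seq_len(k) - (block - 1L) * cfg$ld_block_size
      as.integer(block * 2e7 + within * 1000L)
    }
    snp_id <- sprintf("rs%05d", seq_len(n))
    chrom <- c(rep("1", Jx), rep("2", Jm))
    pos <- c(block_pos(Jx), block_pos(Jm))

    mk <- function(beta, se, trait, type, n_trait) {
      sumstats(data.frame(snp_id = snp_id, chrom = chrom, pos = pos,
                          effect_allele = al$ea, other_allele = al$oa,
                          beta = beta, se = se,
                          pval = pmax(2 * stats::pnorm(-abs(beta / se)),
                                      .Machine$double.xmin),
                          eaf = eaf, n = n_trait,
                          stringsAsFactors = FALSE),
               trait_id = trait, trait_type = type, quiet = TRUE)
    }
    tabs <- list(
      exposure = mk(beta_x, se_x, "exposure_X", "continuous", cfg$n_x),
      mediator = mk(beta_m, se_m, "mediator_M", "continuous", cfg$n_m),
      outcome = mk(beta_y, se_y, "outcome_Y", "binary", cfg$n_y)
    )

    # Block-diagonal r^2 matrix mirroring the noise correlation.
    r2 <- diag(n)
    if (cfg$ld_block_size > 1L && cfg$ld_rho > 0) {
      fill <- function(offset, k) {
        if (k < 2L) return()
        blocks <- split(seq_len(k), ceiling(seq_len(k) / cfg$ld_block_size))
        for (idx in blocks) {
          m <- length(idx)
          if (m < 2L) next
          R <- cfg$ld_rho^abs(outer(seq_len(m), seq_len(m), "-"))
          r2[offset + idx, offset + idx] <<- R^2
        }
      }
      fill(0L, Jx); fill(Jx, Jm)
      diag(r2) <- 1
    }
    ld <- ld_matrix(r2, snp_id, positions = pos)

    if (cfg$harmonization_noise > 0) {
      cseed <- derive_seed(cfg$seed, 9901L)
      tabs <- lapply(tabs, corrupt_encoding,
                     fraction = cfg$harmonization_noise, seed = cseed)
    }

    list(exposure = tabs$exposure, mediator = tabs$mediator,
         outcome = tabs$outcome, ld = ld,
         truth = list(gamma = gamma, delta = delta, pleio = pleio,
                      maf = maf, snp_id = snp_id,
                      tau_true = tau_true,
                      proportion_true = if (tau_true != 0)
                        cfg$alpha * cfg$b_true / tau_true else NA_real_,
                      config = cfg))
  })
}

#' Corrupt allele encodings of a summary-statistics table
#'
#' Applies seeded, semantically controlled encoding hazards to a random
#' subset of SNPs, for exercising harmonization: `"swap"` exchanges effect
#' and other allele with beta negation and frequency complement (the record
#' still describes the same association); `"strand"` complements both
#' alleles (other-strand report of the same variant); `"palindromic"`
#' replaces the allele pair by A/T or C/G with frequency 0.5, making the
#' SNP unresolvable by frequency. The selected subset and corruption types
#' depend only on the seed and the row count, so applying the same call to
#' several tables sharing a SNP panel corrupts the same variants the same
#' way. The applied corruptions are attached as attribute `corruptions`.
#'
#' @param table A `sumstats` object.
#' @param fraction Fraction of SNPs to corrupt, in \[0, 1\].
#' @param seed Integer seed.
#' @param types Subset of `c("swap", "strand", "palindromic")` to draw from.
#' @return The corrupted `sumstats` with attribute `corruptions`, a
#'   data.frame of `snp_id` and `type` (empty when `fraction = 0`).
#' @export
corrupt_encoding <- function(table, fraction, seed,
                             types = c("swap", "strand", "palindromic")) {
  stopifnot(inherits(table, "sumstats"), fraction >= 0, fraction <= 1)
  types <- match.arg(types, several.ok = TRUE)
  n <- nrow(table)
  k <- round(fraction * n)
  out <- table
  if (k == 0L) {
    attr(out, "corruptions") <- data.frame(snp_id = character(0),
                                           type = character(0),
                                           stringsAsFactors = FALSE)
    return(out)
  }
  withr_seed(seed, {
    idx <- sample.int(n, k)
    type <- sample(types, k, replace = TRUE)
    pal_pair <- sample(c("AT", "CG"), k, replace = TRUE)
    for (i in seq_len(k)) {
      j <- idx[i]
      if (type[i] == "swap") {
        ea <- out$effect_allele[j]
        out$effect_allele[j] <- out$other_allele[j]
        out$other_allele[j] <- ea
        out$beta[j] <- -out$beta[j]
        if (!is.na(out$eaf[j])) out$eaf[j] <- 1 - out$eaf[j]
      } else if (type[i] == "strand") {
        out$effect_allele[j] <- complement_allele(out$effect_allele[j])
        out$other_allele[j] <- complement_allele(out$other_allele[j])
      } else {
        out$effect_allele[j] <- if (pal_pair[i] == "AT") "A" else "C"
        out$other_allele[j] <- if (pal_pair[i] == "AT") "T" else "G"
        out$eaf[j] <- 0.5
      }
    }
    attr(out, "corruptions") <- data.frame(snp_id = table$snp_id[idx],
                                           type = type,
                                           stringsAsFactors = FALSE)
    out
  })
}

#' Redraw the outcome table of a simulated world with independent noise
#'
#' Returns a new outcome summary-statistics table generated from the same
#' per-SNP true effects as `sim$outcome` but with fresh sampling noise (and
#' optionally a different sample size) — the situation of a validation GWAS
#' of the same phenotype in an independent cohort.
#'
#' @param sim A result of [simulate_sumstats()].
#' @param seed Integer seed for the new noise draw.
#' @param n_y Sample size of the validation GWAS; defaults to the original.
#' @return A `sumstats` object with trait id `"outcome_Y_validation"`.
#' @export
resample_outcome <- function(sim, seed, n_y = NULL) {
  stopifnot(is.list(sim), !is.null(sim$truth), inherits(sim$outcome, "sumstats"))
  truth <- sim$truth
  cfg <- truth$config
  n_y <- n_y %||% cfg$n_y
  truth_y <- c(truth$tau_true * truth$gamma + sign(truth$gamma) * truth$pleio,
               cfg$b_true * truth$delta)
  se_y <- 1 / sqrt(2 * truth$maf * (1 - truth$maf) * n_y)
  withr_seed(seed, {
    beta <- truth_y + stats::rnorm(length(truth_y)) * se_y
    df <- as.data.frame(sim$outcome)[match(truth$snp_id, sim$outcome$snp_id), ]
    df$beta <- beta
    df$se <- se_y
    df$pval <- pmax(2 * stats::pnorm(-abs(beta / se_y)), .Machine$double.xmin)
    df$n <- n_y
    sumstats(df, "outcome_Y_validation", trait_type = "binary", quiet = TRUE)
  })
}
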