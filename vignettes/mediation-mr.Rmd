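---
title: "Methods: two-sample and two-step mediation MR in medimr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-sample and two-step mediation MR in medimr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(medimr)
```

# The model

Two-sample MR treats each instrument SNP *j* as a natural experiment. With
$\hat\gamma_j$ the SNP–exposure association (standard error
$\sigma_{\gamma j}$) from one GWAS and $\hat\Gamma_j$ the SNP–outcome
association ($\sigma_{\Gamma j}$) from an independent GWAS, the
instrumental-variable assumptions (relevance, independence, exclusion)
imply $\Gamma_j = \beta\,\gamma_j$ for a single causal effect $\beta$.
Every estimator in the package is a way of pooling the per-SNP Wald ratios
$\hat\beta_j = \hat\Gamma_j/\hat\gamma_j$ that remains informative when
some assumptions fail:

* **IVW** weights ratios by $w_j = \hat\gamma_j^2/\sigma_{\Gamma j}^2$ —
  efficient when all instruments are valid, biased under directional
  pleiotropy.
* **MR-Egger** adds an intercept to the weighted regression of
  $\hat\Gamma$ on $\hat\gamma$; the intercept absorbs (and tests)
  directional pleiotropy under the InSIDE assumption, at a substantial
  cost in precision.
* **The weighted median** is consistent while valid instruments carry more
  than half the total weight.
* **Cochran's Q**, the **Egger intercept test**, **MR-PRESSO** and
  **leave-one-out** quantify heterogeneity, directional pleiotropy, and
  single-SNP influence.

For a binary outcome all effects are per-allele log-odds; odds ratios are a
display transform (`or_*` columns) and never enter the arithmetic.

## Two-step mediation

To ask how much of an exposure's effect on the outcome runs through an
intermediate trait M, the package estimates three *univariable* MR effects:
$a$ (exposure → mediator, from the exposure's instruments), $b$ (mediator →
outcome, from the mediator's **own** instruments, e.g. cis-pQTLs) and
$\tau$ (total exposure → outcome). Then

$$\text{indirect} = ab, \qquad \text{direct} = \tau - ab, \qquad
  P = ab/\tau,$$

with first-order delta-method standard errors assuming independence across
the non-overlapping GWAS samples:

$$\mathrm{se}(ab) = \sqrt{a^2\sigma_b^2 + b^2\sigma_a^2}, \qquad
  \mathrm{se}(P) = |P|\sqrt{\tfrac{\sigma_a^2}{a^2} +
  \tfrac{\sigma_b^2}{b^2} + \tfrac{\sigma_\tau^2}{\tau^2}}.$$

The mediation Z statistic is the indirect effect over its SE (a flag
switches the test to the proportion instead), and the screen retains only
mediators whose indirect effect shares the sign of $\tau$ and whose step-1,
step-2 and mediation p-values clear the configured $\alpha$ (default 0.05).
Benjamini–Hochberg FDR is applied within each screen family, never
globally, and the family size is recorded next to each q-value.

Design choices that were genuinely open, and what we chose:

* **Univariable step 2.** The mediator→outcome effect is estimated from
  the mediator's own instruments without multivariable adjustment for the
  exposure. This matches the two-step design the package implements;
  multivariable MR is out of scope.
* **Proportion CI.** The 95% interval is the delta-method interval on $P$
  itself ($P \pm z^{*}\,\mathrm{se}(P)$, exact normal quantile
  $z^{*} \approx 1.959964$). A seeded Monte-Carlo interval
  (`mediation_mc_ci()`) is provided as a cross-check; the two agree
  closely whenever $a$, $b$, $\tau$ are each measured with |effect|/SE
  well above 3.
* **Mediation p-value.** Defined on the indirect effect (Z test), not as a
  joint test of $a$ and $b$.
* **Non-collapsibility.** With a binary outcome the decomposition lives on
  the log-odds scale; the proportion mediated is interpreted on that scale
  and is approximate in the presence of non-collapsibility. No correction
  is attempted.

# Harmonization conventions

The exposure's effect allele defines the frame; the exposure beta is never
flipped. Outcome records are aligned by literal allele match, by swap
(beta negated, frequency complemented), or by strand complement. For
palindromic SNPs (A/T, C/G) the complement coincides with the swap, so
orientation must come from allele frequency:

* `drop_ambiguous` (default): drop palindromic SNPs whose exposure *or*
  outcome effect-allele frequency lies in [0.42, 0.58] or is missing;
  otherwise infer strand from whether the two frequencies sit on the same
  side of 0.5.
* `drop_all`: drop every palindromic SNP.
* `infer_by_freq`: infer from frequency regardless of the window (still
  dropping missing or exactly-0.5 frequencies).

The window [0.42, 0.58] is the conventional conservative default in
two-sample MR software; the analyses this package reproduces do not state
a policy, so the default is documented rather than claimed faithful.
Irreconcilable allele pairs are `dropped_mismatch`. Harmonizing an
already-harmonized set is a no-op, and flipping the allele frame of both
tables leaves every downstream estimate bit-identical — both properties
are enforced by tests.

# Instrument selection

Thresholds follow the field's standard two-sample MR practice, with strict
inequalities throughout: significance $p < 5\times10^{-8}$
($5\times10^{-6}$ for hypothesis-generating screens over many candidate
exposures), $\mathrm{MAF} > 0.01$ (records with missing frequency cannot
be checked and are dropped, with a count), and greedy LD clumping: sort by
ascending p (ties broken by chromosome, then position, for determinism),
take the top SNP as an index, prune remaining SNPs on the same chromosome
within 10,000 kb whose $r^2 \ge 0.001$ with it, repeat. A SNP is pruned
only when *both* the distance and the correlation condition hold; distance
is measured to the index SNP. Brute-force checks on small instances verify
the output is an independent, maximal set. Per-instrument F statistics
$(\hat\gamma_j/\sigma_{\gamma j})^2$ are reported for information; no
F-based filter is applied. For molecular QTL exposures `cis_filter()`
retains SNPs inside the gene body extended by 10 kb (closed interval).

# Numerical conventions

* Wald-ratio SE is first-order ($\sigma_{\Gamma}/|\hat\gamma|$), matching
  the dominant convention; `wald_ratio(second_order = TRUE)` adds the
  exposure-variance term.
* The multiplicative random-effects scale factor is floored at 1: the MRE
  SE never undercuts the fixed-effects SE.
* MR-Egger SEs are scaled by $\max(1, \hat\sigma)$ (residual scale floored
  at 1) with t inference on $J-2$ df; instruments are oriented
  $\hat\gamma_j \ge 0$ before fitting, which is part of the estimator's
  definition because it changes the intercept.
* Weighted-median SE: parametric bootstrap (default 1000 resamples), seed
  mandatory and recorded in the output.
* MR-PRESSO: observed statistic is the leave-one-out weighted residual sum
  of squares; the null is simulated (default 1000 draws) with empirical
  add-one p-values, $(1 + \#\{\mathrm{sim} \ge \mathrm{obs}\})/(n_{sim}+1)$,
  so p is never 0 and never below $1/(n_{sim}+1)$. Outlier p-values are
  Bonferroni-adjusted; flagged SNPs are removed once (no iteration) and an
  outlier-corrected IVW is reported. The distortion test is not
  implemented. Pairs are sorted by SNP id before simulation so results are
  independent of input order.
* Degenerate cases: a zero exposure effect is a hard error for ratios; the
  delta product SE at $a=b=0$ warns (the first-order term vanishes);
  $\tau=0$ leaves the proportion undefined (NA) while the indirect effect
  is still returned.
* Every stochastic routine takes an explicit integer seed and records it;
  pipeline stages derive their seeds deterministically from the master
  seed in `analysis_config()`.

# The synthetic generator

`simulate_sumstats()` emits marginal GWAS summary statistics for three
traits with known causal structure, drawn directly from the asymptotic
sampling distribution of marginal estimates — no individual-level
genotypes, which keeps a full pipeline replicate in the low milliseconds.

The world has $J$ exposure instruments with marginal effects $\gamma_j$
scaled so they explain `h2_x` of the exposure variance, and $J_m$
mediator-specific instruments scaled to `h2_m`. The mediator needs its own
instruments: if every SNP acted on M only through X, step-2 MR with "the
mediator's instruments" would be estimating $\tau/\alpha$, not $b$ — the
design is identified precisely because traits like plasma proteins have
strong cis instruments of their own. True marginal effects are
$\alpha\gamma_j$ and $\delta_k$ on M, and
$(\theta + \alpha b)\gamma_j + \mathrm{sign}(\gamma_j)p_j$ and $b\delta_k$
on Y, where $p_j$ is the horizontal-pleiotropy draw
($N(\mu_p, \sigma_p)$; $\mu_p \ne 0$ gives directional pleiotropy, defined
relative to the exposure-increasing allele so that it biases IVW the way
the MR-Egger literature describes; `pleio_inside = FALSE` correlates $p_j$
with instrument strength to violate InSIDE). Observed effects add noise
with the standard GWAS standard error $1/\sqrt{2f(1-f)n}$.

Default parameters are the study conditions the package is calibrated
under: sample sizes at the scale of contemporary biobank GWAS for the
exposure and outcome ($4.6\times10^5$, $4.8\times10^5$) and of large
proteogenomic cohorts for the mediator ($3.6\times10^4$); $J = 100$,
$J_m = 30$; `h2_x` = 0.05 (a few percent, typical of behavioural/intake
traits), `h2_m` = 0.15 (strong cis control of a plasma protein); and
$(\alpha, b, \theta) = (0.11, 0.11, 0.088)$, giving a true mediated
proportion $\alpha b/(\theta + \alpha b) = 0.1209$ — the order of the
mediated proportions reported for plasma-protein mediators of dietary
exposures. Per-SNP variance contributions are drawn uniformly within a
3-fold range: clumped genome-wide-significant instruments have broadly
comparable strengths, and this keeps mean instrument F high enough
(z ≈ 13–15) that selection at $5\times10^{-8}$ induces negligible
winner's curse in the calibration runs.

LD is emulated at two levels: the emitted $r^2$ matrix has block-diagonal
structure ($r = \rho^{|i-j|}$ within blocks of `ld_block_size`, blocks
20,000 kb apart so they never interact under the default clumping window)
and sampling noise is correlated within blocks with the same $r$. What the
generator does **not** emulate: real genome LD maps, allele-frequency
spectra, sample overlap between the three GWAS, liability-scale binary
traits (the outcome is generated on the log-odds scale directly), and
winner's-curse at marginal instrument strength. Tests passing on this
generator therefore demonstrate correctness of the estimators and
plumbing under the stated model, not robustness to everything real
summary statistics can contain.

`corrupt_encoding()` injects the three harmonization hazards (allele swap
with beta negation, strand complement, conversion to an
ambiguous-frequency palindromic pair) into a seeded subset of SNPs; the
subset depends only on the seed and row count, so applying the same call
to several tables sharing a SNP panel corrupts the same variants
consistently. `resample_outcome()` redraws the outcome table from the same
truth with fresh noise — the validation-GWAS situation.

# Calibration and problem sizes

The acceptance suite (also run by `scripts/acceptance.R`) uses these
problem sizes, chosen to put Monte-Carlo error well inside the asserted
bands while keeping a full run around twenty seconds: Cochran's Q type-I
error at $J=20$ over 2000 null replicates (band $0.05 \pm 0.015$); IVW
95% CI coverage at $J=50$ over 1000 replicates ($95\% \pm 2\%$, asserted
for both the fixed- and multiplicative-random-effects interval);
MR-PRESSO null retention over 200 replicates ($\ge 90\%$ above p = 0.05)
and detection of a 10-SE outlier (global $p \le 0.01$); and mediated
proportion recovery over 500 pipeline replicates (mean within Monte-Carlo
error of 0.121, delta CI coverage $95\% \pm 3\%$). The oracle layer checks
IVW and MR-Egger against `lm(weights = )` to $10^{-10}$, the equal-weight
weighted median against the plain median, and `bh_fdr()` against a
brute-force smallest-rejecting-level search on all input sizes up to 6.

# Known limitations

* No multivariable MR, MR-RAPS, mode-based estimators, Steiger
  directionality filtering, or reverse-direction screens.
* No VCF/GWAS-VCF ingestion, no genome-build liftover, no LD computation
  from genotype panels (the LD matrix is an input).
* The MR-PRESSO distortion test is omitted.
* Proportion-mediated inference on binary outcomes inherits the
  non-collapsibility caveat above.
* The delta-method intervals are first-order; they degrade when any of
  $a$, $b$, $\tau$ is weakly measured (|effect|/SE below ~3), which is
  exactly when the Monte-Carlo cross-check should be consulted.
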