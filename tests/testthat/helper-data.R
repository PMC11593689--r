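# Builders for small in-code fixtures shared across test files.

# A valid summary-statistics record set with overridable fields.
make_records <- function(n = 3, ...) {
  rec <- data.frame(
    snp_id = sprintf("rs%d", seq_len(n)),
    chrom = rep("1", n),
    pos = seq_len(n) * 1000L,
    effect_allele = rep("A", n),
    other_allele = rep("G", n),
    beta = seq_len(n) / 10,
    se = rep(0.05, n),
    pval = rep(1e-9, n),
    eaf = rep(0.3, n),
    n = rep(10000, n),
    stringsAsFactors = FALSE
  )
  dots <- list(...)
  for (nm in names(dots)) rec[[nm]] <- dots[[nm]]
  rec
}

make_table <- function(n = 3, trait_id = "trait", trait_type = "continuous", ...) {
  sumstats(make_records(n, ...), trait_id = trait_id, trait_type = trait_type,
           quiet = TRUE)
}

# A harmonized-pair data.frame straight from effect vectors.
make_pairs <- function(beta_exp, beta_out, se_out, se_exp = 1e-6,
                       snp_id = NULL) {
  J <- length(beta_exp)
  data.frame(
    snp_id = snp_id %||% sprintf("rs%d", seq_len(J)),
    beta_exp = beta_exp,
    se_exp = rep_len(se_exp, J),
    beta_out = beta_out,
    se_out = rep_len(se_out, J),
    eaf = rep(0.3, J),
    f_stat = (beta_exp / rep_len(se_exp, J))^2,
    action = rep("kept_as_is", J),
    stringsAsFactors = FALSE
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Identity LD matrix over a table's SNPs.
identity_ld <- function(table) {
  ld_matrix(diag(nrow(table)), table$snp_id, positions = table$pos)
}
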