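# Instrument selection: significance + MAF filtering, greedy LD clumping,
# cis-window restriction for molecular QTL exposures, LD matrix I/O.

#' Instrument-selection thresholds
#'
#' Defaults follow common two-sample MR practice: genome-wide significance
#' `p < 5e-8` (relaxed to `5e-6` for discovery screens over many candidate
#' exposures), LD pruning at `r^2 < 0.001` within a 10,000 kb window, and a
#' minor-allele-frequency floor of 0.01. All comparisons are strict:
#' `p < p_threshold`, `MAF > maf_min`, prune when `r^2 >= r2_threshold`.
#'
#' @param p_threshold Significance cutoff.
#' @param r2_threshold LD cutoff (squared correlation).
#' @param window_kb Clumping distance in kilobases.
#' @param maf_min Minor-allele-frequency floor.
#' @return A `selection_params` list.
#' @export
selection_params <- function(p_threshold = 5e-8, r2_threshold = 0.001,
                             window_kb = 10000, maf_min = 0.01) {
  stopifnot(p_threshold > 0, r2_threshold > 0, r2_threshold < 1,
            window_kb > 0, window_kb == as.integer(window_kb), maf_min > 0)
  structure(list(p_threshold = p_threshold, r2_threshold = r2_threshold,
                 window_kb = as.integer(window_kb), maf_min = maf_min),
            class = "selection_params")
}

#' Filter SNPs by significance and minor-allele frequency
#'
#' Retains records with `pval < p_threshold` and
#' `min(eaf, 1 - eaf) > maf_min` (strict inequalities). Records with missing
#' `eaf` cannot be MAF-checked and are dropped; their count is attached as
#' attribute `n_missing_eaf`.
#'
#' @param table A `sumstats` object.
#' @param params A [selection_params()] list.
#' @return Filtered `sumstats` object; warns (not errors) when empty.
#' @export
significance_filter <- function(table, params = selection_params()) {
  stopifnot(inherits(table, "sumstats"), inherits(params, "selection_params"))
  maf <- pmin(table$eaf, 1 - table$eaf)
  missing_eaf <- is.na(maf)
  keep <- !missing_eaf & table$pval < params$p_threshold & maf > params$maf_min
  out <- as_sumstats(table[keep, , drop = FALSE], table)
  attr(out, "n_missing_eaf") <- sum(missing_eaf)
  if (nrow(out) == 0L) {
    warning(sprintf("significance_filter: no SNPs pass p < %g, MAF > %g for '%s'",
                    params$p_threshold, params$maf_min, attr(table, "trait_id")))
  }
  out
}

#' Construct an LD matrix object
#'
#' @param r2 Symmetric matrix of squared correlations in \[0, 1\] with unit
#'   diagonal, dimnames optional.
#' @param snp_ids SNP identifiers, one per row/column of `r2`.
#' @param positions Base-pair position per SNP (used only for reporting;
#'   clumping distances come from the summary-statistics table itself).
#' @return An `ld_matrix` list with elements `snp_ids`, `r2`, `positions`.
#' @export
ld_matrix <- function(r2, snp_ids, positions = NULL) {
  r2 <- as.matrix(r2)
  stopifnot(nrow(r2) == ncol(r2), length(snp_ids) == nrow(r2))
  if (any(abs(r2 - t(r2)) > 1e-8)) stop_medimr("r2 matrix not symmetric", "medimr_domain_error")
  if (any(r2 < -1e-12 | r2 > 1 + 1e-12)) stop_medimr("r2 values outside [0,1]", "medimr_domain_error")
  if (any(abs(diag(r2) - 1) > 1e-8)) stop_medimr("r2 diagonal must be 1", "medimr_domain_error")
  dimnames(r2) <- list(snp_ids, snp_ids)
  structure(list(snp_ids = as.character(snp_ids), r2 = r2,
                 positions = positions),
            class = "ld_matrix")
}

#' Read an LD matrix from delimited text
#'
#' Supports two layouts: `"square"`, a TSV whose header row and first column
#' are SNP identifiers framing an r-squared matrix; and `"long"`, a
#' three-column table `snp_a, snp_b, r2` (missing pairs default to 0).
#'
#' @param path File path.
#' @param format `"auto"` (detect from the header), `"square"`, or `"long"`.
#' @return An `ld_matrix` object.
#' @export
read_ld_matrix <- function(path, format = c("auto", "square", "long")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_medimr(paste0("file not found: ", path), "medimr_io_error")
  delim <- .detect_delim(path)
  raw <- utils::read.table(path, header = TRUE, sep = delim,
                           stringsAsFactors = FALSE, check.names = FALSE)
  if (format == "auto") {
    format <- if (ncol(raw) == 3L &&
                  all(tolower(names(raw)) %in% c("snp_a", "snp_b", "r2"))) "long" else "square"
  }
  if (format == "long") {
    names(raw) <- tolower(names(raw))
    ids <- sort(unique(c(raw$snp_a, raw$snp_b)))
    r2 <- diag(length(ids))
    dimnames(r2) <- list(ids, ids)
    r2[cbind(match(raw$snp_a, ids), match(raw$snp_b, ids))] <- raw$r2
    r2[cbind(match(raw$snp_b, ids), match(raw$snp_a, ids))] <- raw$r2
    ld_matrix(r2, ids)
  } else {
    ids <- as.character(raw[[1L]])
    m <- as.matrix(raw[, -1L, drop = FALSE])
    ld_matrix(m, ids)
  }
}

#' Write an LD matrix as a square TSV
#'
#' @param ld An `ld_matrix` object.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_ld_matrix <- function(ld, path) {
  stopifnot(inherits(ld, "ld_matrix"))
  out <- data.frame(SNP = ld$snp_ids, ld$r2, check.names = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Greedy LD clumping of summary statistics
#'
#' Sorts SNPs by ascending p-value (ties broken by chromosome then
#' position), repeatedly takes the top remaining SNP as an index SNP and
#' removes remaining SNPs on the same chromosome within `window_kb` of it
#' whose squared correlation with it is `>= r2_threshold`. Both the distance
#' and the r-squared condition must hold for a SNP to be pruned. The result
#' lists index SNPs in selection order and is fully deterministic.
#'
#' @param table A `sumstats` object.
#' @param ld An [ld_matrix()] covering every SNP in `table`.
#' @param params A [selection_params()] list.
#' @return Clumped `sumstats` with attribute `clump_report`, a data.frame
#'   of removed SNPs and the index SNP each was pruned by.
#' @export
ld_clump <- function(table, ld, params = selection_params()) {
  stopifnot(inherits(table, "sumstats"), inherits(ld, "ld_matrix"),
            inherits(params, "selection_params"))
  missing <- setdiff(table$snp_id, ld$snp_ids)
  if (length(missing) > 0L) {
    stop_medimr(paste0("SNP(s) absent from LD matrix: ",
                       paste(missing, collapse = ", ")),
                "medimr_missing_ld_error")
  }
  if (nrow(table) == 0L) return(as_sumstats(table, table))
  ord <- order(table$pval, table$chrom, table$pos)
  df <- as.data.frame(table)[ord, , drop = FALSE]
  r2 <- ld$r2[df$snp_id, df$snp_id, drop = FALSE]
  window_bp <- params$window_kb * 1000

  alive <- rep(TRUE, nrow(df))
  index <- integer(0)
  removed_by <- character(0); removed_snp <- character(0)
  while (any(alive)) {
    i <- which(alive)[1L]
    index <- c(index, i)
    alive[i] <- FALSE
    cand <- which(alive)
    prune <- cand[df$chrom[cand] == df$chrom[i] &
                    abs(df$pos[cand] - df$pos[i]) <= window_bp &
                    r2[cand, i] >= params$r2_threshold]
    if (length(prune) > 0L) {
      alive[prune] <- FALSE
      removed_snp <- c(removed_snp, df$snp_id[prune])
      removed_by <- c(removed_by, rep(df$snp_id[i], length(prune)))
    }
  }
  out <- as_sumstats(df[index, , drop = FALSE], table)
  attr(out, "clump_report") <- data.frame(removed_snp = removed_snp,
                                          index_snp = removed_by,
                                          stringsAsFactors = FALSE)
  out
}

#' Restrict QTL instruments to a cis window around a gene
#'
#' Retains SNPs on the gene's chromosome with position in the closed
#' interval `[gene_start - flank_kb*1000, gene_end + flank_kb*1000]` — the
#' gene body extended by `flank_kb` (default 10 kb) on each side.
#'
#' @param table A `sumstats` object.
#' @param gene_chrom Chromosome of the gene.
#' @param gene_start,gene_end Gene body bounds in base pairs
#'   (`gene_start <= gene_end`).
#' @param flank_kb Flank size in kilobases.
#' @return Filtered `sumstats` object.
#' @export
cis_filter <- function(table, gene_chrom, gene_start, gene_end, flank_kb = 10) {
  stopifnot(inherits(table, "sumstats"))
  if (gene_start > gene_end) {
    stop_medimr("gene_start must be <= gene_end", "medimr_domain_error")
  }
  lo <- gene_start - flank_kb * 1000
  hi <- gene_end + flank_kb * 1000
  keep <- table$chrom == as.character(gene_chrom) &
    table$pos >= lo & table$pos <= hi
  as_sumstats(table[keep, , drop = FALSE], table)
}

#' Select instruments for an exposure
#'
#' Convenience composition of [significance_filter()] and [ld_clump()].
#'
#' @inheritParams ld_clump
#' @return Clumped, significant `sumstats`.
#' @export
select_instruments <- function(table, ld, params = selection_params()) {
  sig <- suppressWarnings(significance_filter(table, params))
  ld_clump(sig, ld, params)
}
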