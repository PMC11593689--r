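# GWAS-style summary-statistics tables: construction, validation, text I/O.

#' Standard column layout for summary-statistics files
#'
#' The canonical "SNP/CHR/BP/EA/OA/BETA/SE/P/EAF/N" dialect used by many
#' public GWAS downloads. Supply a modified copy to [read_sumstats()] when a
#' file uses different header names.
#'
#' @return Named character vector mapping standard field names to file column
#'   names.
#' @export
#' @examples
#' default_column_map()
default_column_map <- function() {
  c(snp_id = "SNP", chrom = "CHR", pos = "BP",
    effect_allele = "EA", other_allele = "OA",
    beta = "BETA", se = "SE", pval = "P", eaf = "EAF", n = "N")
}

.sumstats_required <- c("snp_id", "chrom", "pos", "effect_allele",
                        "other_allele", "beta", "se", "pval")
.sumstats_optional <- c("eaf", "n")

#' Construct a validated summary-statistics table
#'
#' Builds a `sumstats` object (a data.frame with trait metadata) from per-SNP
#' marginal associations, enforcing the per-record invariants: alleles in
#' A/C/G/T and distinct, `se > 0`, `pval` in (0, 1], `eaf` (when present) in
#' (0, 1), and unique SNP identifiers. Rows violating an invariant are
#' dropped and reported in the `validation_log` attribute; alleles are
#' upper-cased before checking.
#'
#' @param records Data.frame with columns `snp_id`, `chrom`, `pos`,
#'   `effect_allele`, `other_allele`, `beta`, `se`, `pval` and optionally
#'   `eaf`, `n`.
#' @param trait_id Character scalar naming the trait.
#' @param trait_type `"continuous"` or `"binary"`. Binary-trait betas are
#'   interpreted as log-odds throughout.
#' @param quiet Suppress the message summarising rejected rows.
#' @return A `sumstats` object: the validated data.frame with attributes
#'   `trait_id`, `trait_type` and `validation_log` (data.frame of rejected
#'   row numbers and reasons).
#' @export
sumstats <- function(records, trait_id, trait_type = c("continuous", "binary"),
                     quiet = FALSE) {
  trait_type <- match.arg(trait_type)
  stopifnot(is.data.frame(records), is.character(trait_id), length(trait_id) == 1L)
  missing_cols <- setdiff(.sumstats_required, names(records))
  if (length(missing_cols) > 0L) {
    stop_medimr(paste0("missing mandatory column(s): ",
                       paste(missing_cols, collapse = ", ")),
                "medimr_config_error")
  }
  rec <- records
  for (col in setdiff(.sumstats_optional, names(rec))) rec[[col]] <- NA_real_
  rec <- rec[c(.sumstats_required, .sumstats_optional)]

  rec$snp_id <- as.character(rec$snp_id)
  rec$chrom <- as.character(rec$chrom)
  rec$pos <- as.integer(rec$pos)
  rec$effect_allele <- toupper(as.character(rec$effect_allele))
  rec$other_allele <- toupper(as.character(rec$other_allele))
  for (col in c("beta", "se", "pval", "eaf", "n")) rec[[col]] <- as.numeric(rec[[col]])

  reason <- rep(NA_character_, nrow(rec))
  flag <- function(bad, why) ifelse(bad & is.na(reason), why, reason)
  valid_allele <- function(a) !is.na(a) & a %in% c("A", "C", "G", "T")
  reason <- flag(is.na(rec$snp_id) | rec$snp_id == "", "missing snp_id")
  reason <- flag(!valid_allele(rec$effect_allele) | !valid_allele(rec$other_allele),
                 "allele not in A/C/G/T")
  reason <- flag(valid_allele(rec$effect_allele) &
                   rec$effect_allele == rec$other_allele, "identical alleles")
  reason <- flag(is.na(rec$pos) | rec$pos < 1L, "invalid position")
  reason <- flag(!is.finite(rec$beta), "missing/non-finite beta")
  reason <- flag(!is.finite(rec$se) | rec$se <= 0, "se not positive")
  reason <- flag(!is.finite(rec$pval) | rec$pval <= 0 | rec$pval > 1,
                 "pval outside (0,1]")
  reason <- flag(!is.na(rec$eaf) & (rec$eaf <= 0 | rec$eaf >= 1),
                 "eaf outside (0,1)")
  reason <- flag(duplicated(rec$snp_id), "duplicate snp_id")

  bad <- !is.na(reason)
  log <- data.frame(row = which(bad), snp_id = rec$snp_id[bad],
                    reason = reason[bad], stringsAsFactors = FALSE)
  if (nrow(log) > 0L && !quiet) {
    message(sprintf("sumstats('%s'): rejected %d row(s): %s", trait_id, nrow(log),
                    paste(sprintf("row %d (%s)", log$row, log$reason), collapse = "; ")))
  }
  out <- rec[!bad, , drop = FALSE]
  rownames(out) <- NULL
  structure(out,
            trait_id = trait_id, trait_type = trait_type,
            validation_log = log,
            class = c("sumstats", "data.frame"))
}

#' @export
print.sumstats <- function(x, ...) {
  cat(sprintf("<sumstats> trait '%s' (%s), %d SNP(s)\n",
              attr(x, "trait_id"), attr(x, "trait_type"), nrow(x)))
  print.data.frame(utils::head(as.data.frame(x), 10L), ...)
  if (nrow(x) > 10L) cat(sprintf("... %d more row(s)\n", nrow(x) - 10L))
  invisible(x)
}

#' Trait metadata accessors
#'
#' @param x A `sumstats` object.
#' @return `trait_id()` the trait identifier; `trait_type()` `"continuous"`
#'   or `"binary"`.
#' @export
trait_id <- function(x) attr(x, "trait_id")

#' @rdname trait_id
#' @export
trait_type <- function(x) attr(x, "trait_type")

# Rebuild a sumstats object from an already-validated subset of records.
as_sumstats <- function(records, template) {
  structure(`rownames<-`(as.data.frame(records), NULL),
            trait_id = attr(template, "trait_id"),
            trait_type = attr(template, "trait_type"),
            validation_log = attr(template, "validation_log"),
            class = c("sumstats", "data.frame"))
}

.detect_delim <- function(path) {
  header <- readLines(path, n = 1L)
  if (length(header) == 0L) return("\t")
  if (grepl("\t", header, fixed = TRUE)) "\t" else ","
}

#' Read a delimited summary-statistics file
#'
#' Reads a tab- or comma-delimited text table with a header row, renames
#' columns via `column_map`, and validates it with [sumstats()]. A file with
#' a header but no data rows yields an empty table; a file whose data rows
#' are all rejected by validation raises an empty-input error.
#'
#' @param path File path.
#' @param trait_type `"continuous"` or `"binary"`.
#' @param column_map Named character vector as from [default_column_map()];
#'   entries for `eaf`/`n` may point at absent columns.
#' @param trait_id Trait name; defaults to the file name without extension.
#' @param delim `"\t"`, `","`, or `NULL` to auto-detect from the header.
#' @param quiet Passed to [sumstats()].
#' @return A `sumstats` object.
#' @export
read_sumstats <- function(path, trait_type = c("continuous", "binary"),
                          column_map = default_column_map(),
                          trait_id = NULL, delim = NULL, quiet = FALSE) {
  trait_type <- match.arg(trait_type)
  if (!file.exists(path)) stop_medimr(paste0("file not found: ", path), "medimr_io_error")
  delim <- delim %||% .detect_delim(path)
  raw <- utils::read.table(path, header = TRUE, sep = delim,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           na.strings = c("NA", ""), colClasses = "character")
  missing_cols <- setdiff(unname(column_map[.sumstats_required]), names(raw))
  if (length(missing_cols) > 0L) {
    stop_medimr(paste0("missing mandatory column(s) in ", path, ": ",
                       paste(missing_cols, collapse = ", ")),
                "medimr_config_error")
  }
  std <- data.frame(row.names = seq_len(nrow(raw)))
  for (field in c(.sumstats_required, .sumstats_optional)) {
    colname <- column_map[[field]]
    std[[field]] <- if (!is.null(colname) && colname %in% names(raw)) {
      raw[[colname]]
    } else {
      NA_character_
    }
  }
  trait_id <- trait_id %||% sub("\\.[^.]*$", "", basename(path))
  tab <- sumstats(std, trait_id = trait_id, trait_type = trait_type, quiet = quiet)
  if (nrow(tab) == 0L && nrow(raw) > 0L) {
    stop_medimr(paste0("no valid rows in ", path), "medimr_empty_input_error")
  }
  tab
}

#' Write a summary-statistics table
#'
#' Writes the canonical tab-delimited dialect (`SNP CHR BP EA OA BETA SE P
#' EAF N`). Numeric fields are written with 17 significant digits so that
#' `read_sumstats(write_sumstats(x))` reproduces every field exactly; missing
#' optional values are emitted as the literal `NA` token.
#'
#' @param table A `sumstats` object.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_sumstats <- function(table, path) {
  stopifnot(inherits(table, "sumstats"))
  out <- as.data.frame(table)[c(.sumstats_required, .sumstats_optional)]
  names(out) <- unname(default_column_map()[names(out)])
  for (col in c("BETA", "SE", "P", "EAF")) {
    out[[col]] <- ifelse(is.na(out[[col]]), NA_character_,
                         formatC(out[[col]], digits = 17, format = "g"))
  }
  ok <- tryCatch({
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NA")
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop_medimr(paste0("cannot write: ", path), "medimr_io_error")
  invisible(path)
}
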