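#' Default GWAS summary-statistics column mapping
#'
#' Maps the canonical roles used throughout the package to the column names
#' of the common GWAS summary-table dialect. Override individual entries to
#' read tables with other headers, e.g.
#' `gwas_columns(snp = "rsid", pval = "p_value")`.
#'
#' @param ... named overrides, role = column name. Valid roles are
#'   `snp`, `chrom`, `pos`, `effect_allele`, `other_allele`, `eaf`,
#'   `beta`, `se`, `pval`, `n`.
#' @return Named character vector mapping role to column name.
#' @export
#' @examples
#' gwas_columns()
#' gwas_columns(snp = "rsid", eaf = "FRQ")
gwas_columns <- function(...) {
  map <- c(
    snp = "SNP", chrom = "CHR", pos = "POS",
    effect_allele = "EA", other_allele = "OA", eaf = "EAF",
    beta = "BETA", se = "SE", pval = "P", n = "N"
  )
  dots <- c(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(map))
    if (length(bad)) {
      abort(paste0("unknown column role(s): ", paste(bad, collapse = ", ")))
    }
    map[names(dots)] <- dots
  }
  map
}

required_roles <- c("snp", "effect_allele", "other_allele", "beta", "se", "pval")

#' Validate GWAS summary records
#'
#' Checks per-row invariants (alleles are single A/C/G/T bases and differ,
#' `se > 0`, `pval` in (0, 1], `eaf` in \[0, 1\] when present, finite `beta`)
#' and splits a table into valid records and a rejection log.
#'
#' @param tbl a tibble with canonical columns (see [gwas_columns()] roles).
#' @return A list with `records` (valid rows) and `rejections`
#'   (tibble of `row`, `snp`, `reason`).
#' @export
validate_gwas <- function(tbl) {
  base <- c("A", "C", "G", "T")
  reason <- rep(NA_character_, nrow(tbl))
  flag <- function(bad, why) {
    ifelse(is.na(reason) & bad, why, reason)
  }
  reason <- flag(is.na(tbl$snp) | tbl$snp == "", "missing snp id")
  reason <- flag(!(tbl$effect_allele %in% base) | !(tbl$other_allele %in% base),
                 "invalid allele")
  reason <- flag(tbl$effect_allele == tbl$other_allele, "identical alleles")
  reason <- flag(!is.finite(tbl$beta), "nonfinite beta")
  reason <- flag(!is.finite(tbl$se) | tbl$se <= 0, "nonpositive se")
  reason <- flag(!is.finite(tbl$pval) | tbl$pval <= 0 | tbl$pval > 1,
                 "pval outside (0,1]")
  if ("eaf" %in% names(tbl)) {
    reason <- flag(!is.na(tbl$eaf) & (tbl$eaf < 0 | tbl$eaf > 1),
                   "eaf outside [0,1]")
  }
  bad <- !is.na(reason)
  list(
    records = tbl[!bad, , drop = FALSE],
    rejections = tibble(
      row = which(bad),
      snp = as.character(tbl$snp[bad]),
      reason = reason[bad]
    )
  )
}

#' Read a GWAS summary-statistics table
#'
#' Reads a delimited text table (tab or comma, auto-detected from the header
#' line), renames columns to canonical roles via `column_map`, validates each
#' row, and returns the valid records. Rows violating record invariants are
#' dropped and logged in the `"rejections"` attribute.
#'
#' @param path path to a delimited text file with a header.
#' @param column_map role-to-column mapping, see [gwas_columns()]. Must cover
#'   at least snp, effect_allele, other_allele, beta, se, pval.
#' @param delim field delimiter; `NULL` (default) auto-detects tab vs comma.
#' @return A tibble of validated records with canonical column names, with
#'   attribute `"rejections"` (tibble of row, snp, reason).
#' @export
read_gwas_table <- function(path, column_map = gwas_columns(), delim = NULL) {
  if (!file.exists(path)) abort(paste0("cannot read GWAS table: ", path))
  miss <- setdiff(required_roles, names(column_map))
  if (length(miss)) {
    abort(paste0("column_map missing required role(s): ",
                 paste(miss, collapse = ", ")))
  }
  if (is.null(delim)) {
    header <- readLines(path, n = 1L)
    delim <- if (grepl("\t", header)) "\t" else ","
  }
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE)
  missing_cols <- setdiff(unname(column_map), names(raw))
  if (length(missing_cols)) {
    abort(paste0("columns not found in ", path, ": ",
                 paste(missing_cols, collapse = ", ")))
  }
  tbl <- as_gwas_table(raw, column_map)
  v <- validate_gwas(tbl)
  if (nrow(v$records) == 0L) {
    abort(paste0("no valid rows in GWAS table ", path))
  }
  structure(v$records, rejections = v$rejections)
}

#' Convert an in-memory data frame to canonical GWAS columns
#'
#' @param df a data frame holding one trait's summary statistics.
#' @param column_map role-to-column mapping, see [gwas_columns()].
#' @return tibble with canonical role names (`snp`, `chrom`, ..., `n`);
#'   roles absent from `df` are omitted.
#' @export
as_gwas_table <- function(df, column_map = gwas_columns()) {
  present <- column_map[unname(column_map) %in% names(df)]
  out <- as_tibble(df)[unname(present)]
  names(out) <- names(present)
  out$snp <- as.character(out$snp)
  if ("chrom" %in% names(out)) out$chrom <- as.character(out$chrom)
  if ("n" %in% names(out)) out$n <- as.integer(round(out$n))
  out
}

#' Write a GWAS summary-statistics table
#'
#' Inverse of [read_gwas_table()]: renames canonical columns back to the
#' dialect given by `column_map` and writes a delimited text file. readr
#' prints doubles with shortest round-trip precision, so a written table
#' re-reads field-for-field.
#'
#' @param tbl tibble with canonical columns.
#' @param path output file path.
#' @param column_map role-to-column mapping used for the output header.
#' @param delim field delimiter (default tab).
#' @return `path`, invisibly.
#' @export
write_gwas_table <- function(tbl, path, column_map = gwas_columns(),
                             delim = "\t") {
  present <- column_map[names(column_map) %in% names(tbl)]
  out <- tbl[names(present)]
  names(out) <- unname(present)
  readr::write_delim(out, path, delim = delim, progress = FALSE)
  invisible(path)
}

#' Read a pairwise LD table
#'
#' Three-column delimited file: `snp_a`, `snp_b`, `r2`. Lookup is symmetric
#' in (a, b); pairs absent from the table are treated as unknown by
#' consumers (the clumping rule treats unknown pairs inside the window as
#' dependent).
#'
#' @param path path to the delimited LD table.
#' @param delim field delimiter; `NULL` auto-detects tab vs comma.
#' @return tibble with columns `snp_a`, `snp_b`, `r2`.
#' @export
read_ld_table <- function(path, delim = NULL) {
  if (!file.exists(path)) abort(paste0("cannot read LD table: ", path))
  if (is.null(delim)) {
    header <- readLines(path, n = 1L)
    delim <- if (grepl("\t", header)) "\t" else ","
  }
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE)
  if (!all(c("snp_a", "snp_b", "r2") %in% names(raw))) {
    abort("LD table needs columns snp_a, snp_b, r2")
  }
  ld_table(raw$snp_a, raw$snp_b, raw$r2)
}

#' Construct an LD table
#'
#' @param snp_a,snp_b rsID character vectors.
#' @param r2 squared-correlation values in \[0, 1\].
#' @return tibble with columns `snp_a`, `snp_b`, `r2`.
#' @export
ld_table <- function(snp_a = character(), snp_b = character(),
                     r2 = numeric()) {
  stopifnot(length(snp_a) == length(snp_b), length(snp_b) == length(r2))
  if (any(r2 < 0 | r2 > 1)) abort("r2 must lie in [0, 1]")
  tibble(snp_a = as.character(snp_a), snp_b = as.character(snp_b),
         r2 = as.numeric(r2))
}

# Symmetric lookup: named vector keyed on "a|b" in both orders.
ld_lookup <- function(ld) {
  if (is.null(ld) || nrow(ld) == 0L) return(setNames(numeric(), character()))
  keys <- c(paste(ld$snp_a, ld$snp_b, sep = "|"),
            paste(ld$snp_b, ld$snp_a, sep = "|"))
  setNames(c(ld$r2, ld$r2), keys)
}
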