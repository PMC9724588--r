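#' Harmonize exposure and outcome summary statistics
#'
#' Builds the allele-aligned per-SNP effect table that every estimator
#' consumes. Starting from the primary exposure's instrument set, the
#' function: drops palindromic SNPs (A/T, C/G — strand unresolvable);
#' intersects with the outcome table (substituting a high-LD proxy when an
#' instrument is missing from the outcome and an LD table is supplied);
#' intersects with any secondary exposure tables; aligns every trait's
#' effect to the primary exposure's effect allele, negating beta and
#' replacing eaf with 1 - eaf on allele swaps; and drops SNPs significantly
#' associated with the outcome (which would violate the exclusion
#' restriction). Every dropped SNP is logged with exactly one reason code.
#'
#' @param exposures a single instrument tibble, or a named list of them for
#'   multivariable analyses; the first entry is the primary exposure whose
#'   effect alleles define the reference orientation.
#' @param outcome tibble of outcome GWAS records (canonical columns).
#' @param outcome_sig_threshold drop instruments with outcome p-value below
#'   this (default 5e-8).
#' @param ld optional LD table enabling proxy substitution.
#' @param proxy_r2 minimum LD for a proxy (default 0.8, exclusive).
#' @param drop_palindromic drop A/T and C/G SNPs (default TRUE).
#' @param outcome_name label used in downstream estimate tables.
#' @return An `mr_harmonized` tibble with columns `snp`, `chrom`, `pos`,
#'   `effect_allele`, `other_allele`, `eaf`, one `beta_<exposure>` /
#'   `se_<exposure>` / `pval_<exposure>` triple per exposure, and
#'   `beta_out`, `se_out`, `pval_out`. Attributes: `exposures` (names, in
#'   order), `outcome`, `exclusions` (tibble of `snp`, `reason`),
#'   `proxies` (tibble of `snp`, `proxy`, `r2`).
#' @export
mr_harmonize <- function(exposures, outcome, outcome_sig_threshold = 5e-8,
                         ld = NULL, proxy_r2 = 0.8, drop_palindromic = TRUE,
                         outcome_name = "outcome") {
  if (is.data.frame(exposures)) exposures <- list(exposure = exposures)
  if (is.null(names(exposures)) || any(names(exposures) == "")) {
    names(exposures) <- paste0("exposure", seq_along(exposures))
  }
  k <- length(exposures)
  exp_names <- names(exposures)
  primary <- as_tibble(exposures[[1]])
  stopifnot(nrow(primary) > 0)

  excl <- tibble(snp = character(), reason = character())
  note <- function(snps, reason) {
    if (length(snps)) {
      excl <<- dplyr::bind_rows(excl, tibble(snp = snps, reason = reason))
    }
  }

  dup <- duplicated(primary$snp)
  note(primary$snp[dup], "duplicate")
  primary <- primary[!dup, , drop = FALSE]

  if (drop_palindromic) {
    pal <- is_palindromic(primary$effect_allele, primary$other_allele)
    note(primary$snp[pal], "palindromic")
    primary <- primary[!pal, , drop = FALSE]
  }

  # Outcome lookup, with proxy substitution for instruments the outcome
  # table lacks. A proxy's effect allele is taken as concordant with the
  # index SNP's exposure-increasing allele (r2 > proxy_r2); no allele check
  # is possible across distinct variants.
  proxies <- tibble(snp = character(), proxy = character(), r2 = numeric())
  out_idx <- match(primary$snp, outcome$snp)
  lk <- ld_lookup(ld)
  is_proxy <- rep(FALSE, nrow(primary))
  for (i in which(is.na(out_idx))) {
    p <- find_proxy(primary$snp[i], outcome$snp, ld, min_r2 = proxy_r2)
    if (!is.na(p)) {
      out_idx[i] <- match(p, outcome$snp)
      is_proxy[i] <- TRUE
      proxies <- dplyr::bind_rows(proxies, tibble(
        snp = primary$snp[i], proxy = p,
        r2 = unname(lk[paste(primary$snp[i], p, sep = "|")])
      ))
    }
  }
  miss <- is.na(out_idx)
  note(primary$snp[miss], "missing-in-outcome")
  primary <- primary[!miss, , drop = FALSE]
  out_rows <- outcome[out_idx[!miss], , drop = FALSE]
  is_proxy <- is_proxy[!miss]

  align <- function(rows, skip_check = rep(FALSE, nrow(rows))) {
    same <- rows$effect_allele == primary$effect_allele &
      rows$other_allele == primary$other_allele
    swap <- rows$effect_allele == primary$other_allele &
      rows$other_allele == primary$effect_allele
    ok <- same | swap | skip_check
    beta <- ifelse(swap & !skip_check, -rows$beta, rows$beta)
    eaf <- if ("eaf" %in% names(rows)) {
      ifelse(swap & !skip_check, 1 - rows$eaf, rows$eaf)
    } else rep(NA_real_, nrow(rows))
    list(ok = ok, beta = beta, se = rows$se, pval = rows$pval, eaf = eaf)
  }

  out_al <- align(out_rows, skip_check = is_proxy)
  keep <- out_al$ok
  note(primary$snp[!keep], "allele-mismatch")
  primary <- primary[keep, , drop = FALSE]
  out_al <- lapply(out_al, `[`, keep)

  sec <- list()
  if (k > 1) {
    for (j in 2:k) {
      tbl <- as_tibble(exposures[[j]])
      idx <- match(primary$snp, tbl$snp)
      miss <- is.na(idx)
      note(primary$snp[miss], "missing-in-exposure")
      primary <- primary[!miss, , drop = FALSE]
      out_al <- lapply(out_al, `[`, !miss)
      sec <- lapply(sec, function(s) lapply(s, `[`, !miss))
      rows <- tbl[idx[!miss], , drop = FALSE]
      al <- align(rows)
      keep <- al$ok
      note(primary$snp[!keep], "allele-mismatch")
      primary <- primary[keep, , drop = FALSE]
      out_al <- lapply(out_al, `[`, keep)
      sec <- lapply(sec, function(s) lapply(s, `[`, keep))
      sec[[exp_names[j]]] <- lapply(al, `[`, keep)
    }
  }

  sig <- out_al$pval < outcome_sig_threshold
  note(primary$snp[sig], "outcome-significant")
  primary <- primary[!sig, , drop = FALSE]
  out_al <- lapply(out_al, `[`, !sig)
  sec <- lapply(sec, function(s) lapply(s, `[`, !sig))

  j <- nrow(primary)
  min_needed <- if (k == 1) 3L else k + 2L
  if (j < min_needed) {
    abort(sprintf(
      "only %d SNP(s) survive harmonization; need at least %d for %s analysis",
      j, min_needed, if (k == 1) "univariable" else "multivariable"))
  }

  h <- tibble(
    snp = primary$snp,
    chrom = if ("chrom" %in% names(primary)) primary$chrom else NA_character_,
    pos = if ("pos" %in% names(primary)) primary$pos else NA_integer_,
    effect_allele = primary$effect_allele,
    other_allele = primary$other_allele,
    eaf = if ("eaf" %in% names(primary)) primary$eaf else NA_real_
  )
  h[[paste0("beta_", exp_names[1])]] <- primary$beta
  h[[paste0("se_", exp_names[1])]] <- primary$se
  h[[paste0("pval_", exp_names[1])]] <- primary$pval
  for (nm in names(sec)) {
    h[[paste0("beta_", nm)]] <- sec[[nm]]$beta
    h[[paste0("se_", nm)]] <- sec[[nm]]$se
    h[[paste0("pval_", nm)]] <- sec[[nm]]$pval
  }
  h$beta_out <- out_al$beta
  h$se_out <- out_al$se
  h$pval_out <- out_al$pval

  new_mr_harmonized(h, exposures = exp_names, outcome = outcome_name,
                    exclusions = excl, proxies = proxies)
}

new_mr_harmonized <- function(tbl, exposures, outcome = "outcome",
                              exclusions = tibble(snp = character(),
                                                  reason = character()),
                              proxies = NULL) {
  structure(as_tibble(tbl),
            exposures = exposures, outcome = outcome,
            exclusions = exclusions, proxies = proxies,
            class = c("mr_harmonized", class(as_tibble(tbl))))
}

#' Construct a harmonized set directly from effect vectors
#'
#' Convenience constructor for simulation studies and tests where allele
#' bookkeeping has already been resolved: supply per-SNP exposure and
#' outcome effects and standard errors directly.
#'
#' @param beta_exp numeric vector of exposure effects, or a matrix with one
#'   named column per exposure for multivariable input.
#' @param se_exp matching standard errors (vector or matrix), > 0.
#' @param beta_out,se_out outcome effects and standard errors.
#' @param snp optional rsIDs (defaults to snp1, snp2, ...).
#' @param exposure exposure name(s); ignored when `beta_exp` has colnames.
#' @param outcome outcome label.
#' @return an `mr_harmonized` tibble.
#' @export
#' @examples
#' h <- mr_input(beta_exp = c(0.1, 0.12, 0.09), se_exp = rep(0.01, 3),
#'               beta_out = c(0.02, 0.025, 0.018), se_out = rep(0.01, 3))
#' mr_ivw(h)
mr_input <- function(beta_exp, se_exp, beta_out, se_out, snp = NULL,
                     exposure = "exposure", outcome = "outcome") {
  beta_exp <- as.matrix(beta_exp)
  se_exp <- as.matrix(se_exp)
  k <- ncol(beta_exp)
  nms <- colnames(beta_exp) %||% if (k == 1) exposure else
    paste0(exposure, seq_len(k))
  if (any(se_exp <= 0) || any(se_out <= 0)) abort("standard errors must be positive")
  j <- nrow(beta_exp)
  stopifnot(length(beta_out) == j, length(se_out) == j)
  snp <- snp %||% paste0("snp", seq_len(j))
  tbl <- tibble(snp = as.character(snp))
  for (i in seq_len(k)) {
    tbl[[paste0("beta_", nms[i])]] <- beta_exp[, i]
    tbl[[paste0("se_", nms[i])]] <- se_exp[, i]
  }
  tbl$beta_out <- beta_out
  tbl$se_out <- se_out
  new_mr_harmonized(tbl, exposures = nms, outcome = outcome)
}

#' Exposure names of a harmonized set
#' @param h an `mr_harmonized` tibble (or any tibble with `beta_*` columns).
#' @return character vector of exposure names, primary first.
#' @export
exposure_names <- function(h) {
  nms <- attr(h, "exposures")
  if (!is.null(nms)) return(nms)
  cand <- grep("^beta_", names(h), value = TRUE)
  setdiff(sub("^beta_", "", cand), "out")
}

#' Exclusion log of a harmonized set
#' @param h an `mr_harmonized` tibble.
#' @return tibble of `snp`, `reason` for every SNP dropped en route.
#' @export
exclusions <- function(h) {
  attr(h, "exclusions") %||% tibble(snp = character(), reason = character())
}

# Per-SNP vectors for one exposure against the outcome.
h_vectors <- function(h, exposure = NULL) {
  nms <- exposure_names(h)
  exposure <- exposure %||% nms[1]
  if (!exposure %in% nms) abort(paste0("unknown exposure: ", exposure))
  list(snp = h$snp %||% paste0("snp", seq_len(nrow(h))),
       x = h[[paste0("beta_", exposure)]],
       sx = h[[paste0("se_", exposure)]],
       y = h$beta_out, sy = h$se_out,
       exposure = exposure,
       outcome = attr(h, "outcome") %||% "outcome")
}

# J x K matrices across all (or selected) exposures.
exposure_matrix <- function(h, exposures = NULL, what = "beta") {
  nms <- exposures %||% exposure_names(h)
  m <- sapply(nms, function(nm) h[[paste0(what, "_", nm)]])
  matrix(m, nrow = nrow(h), ncol = length(nms),
         dimnames = list(NULL, nms))
}

#' @export
print.mr_harmonized <- function(x, ...) {
  nms <- exposure_names(x)
  cat(sprintf("<mr_harmonized> %d SNPs, exposure(s): %s, outcome: %s\n",
              nrow(x), paste(nms, collapse = ", "),
              attr(x, "outcome") %||% "outcome"))
  ex <- exclusions(x)
  if (nrow(ex)) {
    tab <- table(ex$reason)
    cat("excluded:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
        "\n")
  }
  NextMethod()
}
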