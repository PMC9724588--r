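#' Select genome-wide significant instruments
#'
#' Keeps records with association p-value strictly below the threshold.
#' The conventional genome-wide threshold is 5e-8; a relaxed threshold
#' (e.g. 1e-5) can be supplied for traits with few significant hits.
#'
#' @param records tibble of GWAS records (canonical columns).
#' @param p_threshold selection p-value threshold in (0, 1).
#' @return tibble of retained records, with attributes `selection_pvalue`.
#' @export
select_instruments <- function(records, p_threshold = 5e-8) {
  stopifnot(is.numeric(p_threshold), p_threshold > 0, p_threshold < 1)
  kept <- dplyr::filter(records, .data$pval < p_threshold)
  if (nrow(kept) == 0L) {
    abort(paste0("no instruments pass the selection threshold p < ",
                 format(p_threshold)))
  }
  structure(as_tibble(kept), selection_pvalue = p_threshold)
}

#' Is an allele pair palindromic?
#'
#' A/T and C/G pairs read the same on both strands, so their orientation
#' cannot be resolved from allele labels alone; harmonization drops them.
#'
#' @param effect_allele,other_allele single-base allele codes (A/C/G/T).
#' @return logical, vectorized over the inputs.
#' @export
#' @examples
#' is_palindromic("A", "T")  # TRUE
#' is_palindromic("A", "G")  # FALSE
is_palindromic <- function(effect_allele, other_allele) {
  pair <- paste0(pmin(effect_allele, other_allele),
                 pmax(effect_allele, other_allele))
  pair %in% c("AT", "CG")
}

#' Greedy LD clumping
#'
#' Sorts instruments by ascending p-value (ties broken by rsID) and accepts
#' each SNP unless it lies within `window_bp` of an already-accepted SNP on
#' the same chromosome and is correlated with it (LD r-squared at or above
#' `r2_max`, or the pair is absent from the LD table — absent pairs inside
#' the window are conservatively treated as dependent, since the reference
#' panel used to build `ld` may simply not ship the pair).
#'
#' @param instruments tibble with at least `snp`, `chrom`, `pos`, `pval`.
#' @param ld an LD table from [ld_table()] or [read_ld_table()]; `NULL`
#'   means no pairs are known (everything inside the window collapses).
#' @param r2_max independence threshold (default 0.001).
#' @param window_bp clumping window in base pairs, applied as +/- window
#'   around each accepted index SNP (default 1 Mb).
#' @return tibble of retained (index) SNPs in the input's row order, with
#'   attribute `"clumped"`: a tibble of removed SNPs (`snp`, `index_snp`,
#'   `reason = "clumped"`).
#' @export
clump_instruments <- function(instruments, ld = NULL, r2_max = 0.001,
                              window_bp = 1e6) {
  stopifnot(nrow(instruments) > 0, r2_max > 0, r2_max < 1, window_bp > 0)
  if (!all(c("chrom", "pos") %in% names(instruments))) {
    abort("clumping needs chrom and pos columns")
  }
  lk <- ld_lookup(ld)
  ord <- order(instruments$pval, instruments$snp)
  cand <- instruments[ord, , drop = FALSE]
  accepted <- integer()
  removed <- tibble(snp = character(), index_snp = character(),
                    reason = character())
  for (i in seq_len(nrow(cand))) {
    index_hit <- NA_character_
    for (a in accepted) {
      if (cand$chrom[i] != cand$chrom[a]) next
      if (abs(cand$pos[i] - cand$pos[a]) > window_bp) next
      r2 <- unname(lk[paste(cand$snp[i], cand$snp[a], sep = "|")])
      if (is.na(r2) || r2 >= r2_max) {
        index_hit <- cand$snp[a]
        break
      }
    }
    if (is.na(index_hit)) {
      accepted <- c(accepted, i)
    } else {
      removed <- dplyr::bind_rows(removed, tibble(
        snp = cand$snp[i], index_snp = index_hit, reason = "clumped"
      ))
    }
  }
  kept <- instruments[instruments$snp %in% cand$snp[accepted], , drop = FALSE]
  structure(as_tibble(kept), clumped = removed,
            selection_pvalue = attr(instruments, "selection_pvalue"))
}

#' Find a proxy SNP present in the outcome table
#'
#' Among outcome-present SNPs with LD r-squared strictly above `min_r2` to
#' the query, returns the one with the highest r-squared (ties broken by
#' lexicographically smallest rsID), or `NA` if none qualifies.
#'
#' @param snp_id the query rsID (missing from the outcome).
#' @param outcome_snp_ids character vector of rsIDs present in the outcome.
#' @param ld an LD table.
#' @param min_r2 minimum LD (default 0.8, exclusive).
#' @return a single rsID, or `NA_character_`.
#' @export
find_proxy <- function(snp_id, outcome_snp_ids, ld, min_r2 = 0.8) {
  if (is.null(ld) || nrow(ld) == 0L) return(NA_character_)
  hits <- dplyr::bind_rows(
    dplyr::filter(ld, .data$snp_a == snp_id) |>
      dplyr::transmute(partner = .data$snp_b, r2 = .data$r2),
    dplyr::filter(ld, .data$snp_b == snp_id) |>
      dplyr::transmute(partner = .data$snp_a, r2 = .data$r2)
  )
  hits <- dplyr::filter(hits, .data$partner %in% outcome_snp_ids,
                        .data$partner != snp_id, .data$r2 > min_r2)
  if (nrow(hits) == 0L) return(NA_character_)
  hits <- dplyr::arrange(hits, dplyr::desc(.data$r2), .data$partner)
  hits$partner[1]
}

#' Per-SNP instrument-strength F statistic
#'
#' `F = beta^2 / se^2`, the square of the association z-score; values above
#' 10 are the conventional bar against weak-instrument bias.
#'
#' @param beta per-allele effect estimate(s).
#' @param se standard error(s), > 0.
#' @return numeric vector of F statistics.
#' @export
#' @examples
#' f_statistic(0.1, 0.02)  # 25
f_statistic <- function(beta, se) {
  if (any(se <= 0)) abort("se must be positive")
  beta^2 / se^2
}

#' Per-SNP variance explained
#'
#' `R^2 = 2 * EAF * (1 - EAF) * beta^2` for a trait in SD units under
#' Hardy-Weinberg equilibrium.
#'
#' @param eaf effect-allele frequency in \[0, 1\] (may be `NA`).
#' @param beta per-allele effect in SD units.
#' @return numeric vector of variance-explained contributions (`NA` where
#'   `eaf` is missing).
#' @export
#' @examples
#' variance_explained(0.5, 0.2)  # 0.02
variance_explained <- function(eaf, beta) {
  if (any(eaf < 0 | eaf > 1, na.rm = TRUE)) abort("eaf must lie in [0, 1]")
  2 * eaf * (1 - eaf) * beta^2
}

#' Instrument-strength summary for one exposure
#'
#' Aggregates per-SNP F statistics and variance-explained contributions.
#' The headline per-exposure F is the arithmetic mean of per-SNP F (min and
#' median are also reported); total R-squared is the sum of per-SNP
#' contributions over SNPs with a known effect-allele frequency. A warning
#' is emitted when mean F < 10 (weak instruments) and when any `eaf` is
#' missing (those SNPs are excluded from the R-squared total).
#'
#' @param instruments tibble with `snp`, `beta`, `se` and ideally `eaf`.
#' @return one-row tibble (`n_snp`, `mean_f`, `min_f`, `median_f`,
#'   `total_r2`, `n_missing_eaf`) with attribute `"per_snp"` holding the
#'   per-SNP `f` and `r2` values.
#' @export
strength_summary <- function(instruments) {
  stopifnot(nrow(instruments) > 0)
  f <- f_statistic(instruments$beta, instruments$se)
  eaf <- if ("eaf" %in% names(instruments)) instruments$eaf else
    rep(NA_real_, nrow(instruments))
  r2 <- variance_explained(eaf, instruments$beta)
  n_miss <- sum(is.na(r2))
  if (n_miss > 0) {
    warn(paste0(n_miss, " SNP(s) lack eaf; excluded from total_r2"))
  }
  mean_f <- mean(f)
  if (mean_f < 10) {
    warn(sprintf("mean F = %.2f < 10: possible weak-instrument bias", mean_f))
  }
  structure(
    tibble(
      n_snp = nrow(instruments),
      mean_f = mean_f,
      min_f = min(f),
      median_f = median(f),
      total_r2 = sum(r2, na.rm = TRUE),
      n_missing_eaf = n_miss
    ),
    per_snp = tibble(snp = instruments$snp, f = f, r2 = r2)
  )
}
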