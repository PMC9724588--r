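#' MR-PRESSO: pleiotropy residual sum and outlier test
#'
#' Simulation-based detection of horizontal pleiotropy. The observed
#' global statistic is the weighted residual sum of squares
#' `RSS = sum_j w_j (beta_out_j - beta_exp_j * theta_(-j))^2`, where
#' `theta_(-j)` is the leave-one-out IVW slope and `w_j = 1/se_out_j^2`.
#' Its null distribution is built from `n_sim` parametric draws
#' `beta_exp* ~ N(beta_exp, se_exp^2)`,
#' `beta_out* ~ N(beta_exp * theta_(-j), se_out^2)`, recomputing the RSS
#' on each draw; empirical p-values use the add-one rule
#' `(1 + #{sim >= obs}) / (n_sim + 1)`, so they are never zero. Per-SNP
#' outliers are flagged when their empirical residual p-value falls below
#' `alpha / J` (Bonferroni; set `multiplicity = "none"` for raw alpha).
#' When outliers are flagged, the distortion test compares the relative
#' shift of the IVW estimate after their removal against the shifts from
#' removing equally many random SNPs, and the outlier-corrected estimate
#' is the IVW fit on the retained SNPs.
#'
#' Missing exposure-side SEs degenerate the corresponding draws to a fixed
#' `beta_exp` (a message is emitted). Identical inputs, seed and `n_sim`
#' reproduce the result bit for bit.
#'
#' @inheritParams mr_ivw
#' @param n_sim simulated null draws (default 1000, minimum 1000).
#' @param seed integer seed (required).
#' @param alpha outlier-test significance level (default 0.05).
#' @param multiplicity `"bonferroni"` (flag at `alpha/J`) or `"none"`.
#' @param n_distortion random removal sets for the distortion null.
#' @param mode IVW mode for the raw and corrected estimates.
#' @return object of class `mr_presso`: `global_rss`, `global_pval`,
#'   `per_snp` (tibble of `snp`, `residual_stat`, `pval`, `outlier`),
#'   `outlier_ids`, `distortion_pct`, `distortion_pval`, `raw` and
#'   `corrected` (`mr_estimate`s), `n_sim`, `seed`.
#' @export
mr_presso <- function(h, n_sim = 1000, seed, alpha = 0.05,
                      multiplicity = c("bonferroni", "none"),
                      n_distortion = 1000,
                      mode = c("fixed", "random"), exposure = NULL) {
  multiplicity <- match.arg(multiplicity)
  mode <- match.arg(mode)
  if (missing(seed)) abort("a seed is required for reproducibility")
  stopifnot(n_sim >= 1000)
  v <- h_vectors(h, exposure)
  j <- length(v$x)
  if (j < 4L) abort("MR-PRESSO needs at least 4 SNPs")

  x <- v$x; y <- v$y; sy <- v$sy
  sx <- v$sx
  if (anyNA(sx)) {
    inform("missing exposure-side SEs: those draws use a fixed beta_exp")
    sx[is.na(sx)] <- 0
  }
  w <- 1 / sy^2

  loo_slopes <- function(xx, yy) {
    sxy <- sum(w * xx * yy)
    sxx <- sum(w * xx^2)
    (sxy - w * xx * yy) / (sxx - w * xx^2)
  }
  t_loo <- loo_slopes(x, y)
  resid_obs <- y - x * t_loo
  stat_obs <- w * resid_obs^2
  rss_obs <- sum(stat_obs)

  set.seed(seed)
  xs <- matrix(rnorm(j * n_sim, mean = x, sd = sx), nrow = j)
  ys <- matrix(rnorm(j * n_sim, mean = x * t_loo, sd = sy), nrow = j)
  sxy_s <- colSums(w * xs * ys)
  sxx_s <- colSums(w * xs^2)
  t_loo_s <- (rep(sxy_s, each = j) - w * xs * ys) /
    (rep(sxx_s, each = j) - w * xs^2)
  stat_s <- w * (ys - xs * t_loo_s)^2
  rss_s <- colSums(stat_s)

  global_pval <- (1 + sum(rss_s >= rss_obs)) / (n_sim + 1)
  pvals <- (1 + rowSums(stat_s >= stat_obs)) / (n_sim + 1)
  cut <- if (multiplicity == "bonferroni") alpha / j else alpha
  outlier <- pvals < cut
  outlier_ids <- v$snp[outlier]

  raw <- mr_ivw(h, mode = mode, exposure = exposure)

  distortion_pct <- NA_real_
  distortion_pval <- NA_real_
  corrected <- raw
  if (length(outlier_ids)) {
    if (all(outlier)) abort("every SNP flagged as outlier; no corrected estimate")
    keep <- !outlier
    sub <- mr_input(x[keep], sx[keep], y[keep], sy[keep], snp = v$snp[keep],
                    exposure = v$exposure, outcome = v$outcome)
    corrected <- mr_ivw(sub, mode = mode)
    corrected$method <- "presso_corrected"
    m <- sum(outlier)
    distortion_pct <- 100 * (corrected$theta - raw$theta) / abs(raw$theta)
    ivw_theta <- function(idx_keep) {
      wi <- x[idx_keep]^2 / sy[idx_keep]^2
      sum(wi * y[idx_keep] / x[idx_keep]) / sum(wi)
    }
    d_null <- vapply(seq_len(n_distortion), function(b) {
      drop <- sample.int(j, m)
      100 * (ivw_theta(setdiff(seq_len(j), drop)) - raw$theta) /
        abs(raw$theta)
    }, numeric(1))
    distortion_pval <- (1 + sum(abs(d_null) >= abs(distortion_pct))) /
      (n_distortion + 1)
  }

  structure(list(
    global_rss = rss_obs, global_pval = global_pval,
    per_snp = tibble(snp = v$snp, residual_stat = stat_obs,
                     pval = pvals, outlier = outlier),
    outlier_ids = outlier_ids,
    distortion_pct = distortion_pct, distortion_pval = distortion_pval,
    raw = raw, corrected = corrected,
    n_sim = as.integer(n_sim), seed = as.integer(seed),
    alpha = alpha, multiplicity = multiplicity
  ), class = "mr_presso")
}

#' @export
print.mr_presso <- function(x, ...) {
  cat(sprintf("<mr_presso> global RSS = %.3f, p = %.4g (%d sims, seed %d)\n",
              x$global_rss, x$global_pval, x$n_sim, x$seed))
  if (length(x$outlier_ids)) {
    cat("outliers:", paste(x$outlier_ids, collapse = ", "), "\n")
    cat(sprintf("distortion: %.1f%% (p = %.3g)\n",
                x$distortion_pct, x$distortion_pval))
    cat("corrected estimate:\n")
    print(x$corrected)
  } else {
    cat("no outliers flagged\n")
  }
  invisible(x)
}

#' @export
tidy.mr_presso <- function(x, ...) {
  out <- tidy(x$raw)
  if (length(x$outlier_ids)) out <- dplyr::bind_rows(out, tidy(x$corrected))
  out
}

#' @export
glance.mr_presso <- function(x, ...) {
  tibble(global_rss = x$global_rss, global_pval = x$global_pval,
         n_outliers = length(x$outlier_ids),
         distortion_pct = x$distortion_pct,
         distortion_pval = x$distortion_pval,
         n_sim = x$n_sim, seed = x$seed)
}
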