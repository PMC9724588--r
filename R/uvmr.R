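#' Construct an MR estimate
#'
#' Internal-facing constructor used by every estimator. The causal effect
#' `theta` is on the log-odds-per-SD scale for a binary outcome (SD-per-SD
#' for a continuous one); confidence bounds are normal-theory 95% limits
#' and the odds-ratio scale is the elementwise exponential.
#'
#' @param method method tag (`ivw_fe`, `ivw_mre`, `egger_slope`,
#'   `egger_intercept`, `weighted_median`, `wald`, `mvmr`,
#'   `presso_corrected`).
#' @param theta point estimate.
#' @param se standard error.
#' @param n_snp number of instruments used.
#' @param exposure,outcome trait labels.
#' @param adjusted_for co-exposures adjusted for (multivariable methods).
#' @return object of class `mr_estimate`.
#' @export
mr_estimate <- function(method, theta, se, n_snp,
                        exposure = "exposure", outcome = "outcome",
                        adjusted_for = character()) {
  stopifnot(is.numeric(theta), is.numeric(se), length(theta) == 1L)
  z <- qnorm(0.975)
  pval <- if (is.na(se) || se == 0) NA_real_ else
    2 * pnorm(-abs(theta) / se)
  structure(list(
    method = method, exposure = exposure, outcome = outcome,
    adjusted_for = adjusted_for,
    theta = theta, se = se,
    ci_low = theta - z * se, ci_high = theta + z * se,
    pval = pval,
    or = exp(theta), or_ci_low = exp(theta - z * se),
    or_ci_high = exp(theta + z * se),
    n_snp = as.integer(n_snp)
  ), class = "mr_estimate")
}

#' @export
print.mr_estimate <- function(x, ...) {
  cat(sprintf(
    "<mr_estimate:%s> %s -> %s%s | %d SNPs\n  b = %.4f (se %.4f), OR = %.3f [%.3f, %.3f], p = %.3g\n",
    x$method, x$exposure, x$outcome,
    if (length(x$adjusted_for)) paste0(" (adj. ", paste(x$adjusted_for, collapse = ", "), ")") else "",
    x$n_snp, x$theta, x$se, x$or, x$or_ci_low, x$or_ci_high, x$pval))
  invisible(x)
}

#' Tidy an MR estimate into a one-row tibble
#'
#' Columns follow the forest-plot-ready layout: method, exposure, outcome,
#' adjusted_for, nsnp, b, se, ci_low, ci_high, pval, or, or_ci_low,
#' or_ci_high.
#'
#' @param x an `mr_estimate`.
#' @param ... unused.
#' @export
tidy.mr_estimate <- function(x, ...) {
  tibble(
    method = x$method, exposure = x$exposure, outcome = x$outcome,
    adjusted_for = paste(x$adjusted_for, collapse = "+"),
    nsnp = x$n_snp, b = x$theta, se = x$se,
    ci_low = x$ci_low, ci_high = x$ci_high, pval = x$pval,
    or = x$or, or_ci_low = x$or_ci_low, or_ci_high = x$or_ci_high
  )
}

#' @export
glance.mr_estimate <- function(x, ...) {
  d <- x$diagnostics %||% tibble(q = NA_real_, q_df = NA_integer_,
                                 q_pval = NA_real_)
  dplyr::bind_cols(tibble(method = x$method, nsnp = x$n_snp), d)
}

#' Per-SNP Wald ratio
#'
#' The single-instrument causal estimate: outcome effect divided by
#' exposure effect. The default standard error is first order,
#' `se_y / |beta_x|`, which ignores exposure-side noise and is the
#' convention for strong instruments (F > 10); `second_order = TRUE` adds
#' the exposure-side term `beta_y^2 se_x^2 / beta_x^4` under the radical.
#'
#' @param beta_x,se_x exposure effect and its SE.
#' @param beta_y,se_y outcome effect and its SE.
#' @param second_order use the second-order SE (default FALSE).
#' @return list with `theta` and `se` (vectorized over SNPs).
#' @export
#' @examples
#' wald_ratio(1, 0.1, 0.2, 0.05)  # theta 0.2, se 0.05
wald_ratio <- function(beta_x, se_x, beta_y, se_y, second_order = FALSE) {
  if (any(beta_x == 0)) abort("beta_x = 0: Wald ratio undefined")
  theta <- beta_y / beta_x
  se <- if (second_order) {
    sqrt(se_y^2 / beta_x^2 + beta_y^2 * se_x^2 / beta_x^4)
  } else {
    se_y / abs(beta_x)
  }
  list(theta = theta, se = se)
}

# Closed-form IVW pieces shared by several callers.
ivw_core <- function(x, sx, y, sy) {
  wr <- wald_ratio(x, sx, y, sy)
  w <- 1 / wr$se^2
  theta <- sum(w * wr$theta) / sum(w)
  se_fe <- sqrt(1 / sum(w))
  q <- sum(w * (wr$theta - theta)^2)
  list(theta = theta, se_fe = se_fe, q = q, j = length(x),
       ratios = wr$theta, w = w)
}

#' Inverse-variance-weighted estimate
#'
#' Meta-analyses the per-SNP Wald ratios with inverse-variance weights;
#' algebraically identical to weighted least squares of `beta_out` on
#' `beta_exp` through the origin with weights `1/se_out^2`. The
#' `"fixed"` mode uses the fixed-effect SE; the `"random"` mode
#' (multiplicative random effects) scales it by `sqrt(Q/(J-1))` with no
#' lower truncation at 1, so under-dispersed data can yield a smaller SE
#' than fixed effects. Both modes share the same point estimate.
#'
#' @param h an `mr_harmonized` tibble (see [mr_harmonize()], [mr_input()]).
#' @param mode `"fixed"` or `"random"`.
#' @param exposure which exposure column to use (default: primary).
#' @return an `mr_estimate` (method `ivw_fe` or `ivw_mre`) whose
#'   `diagnostics` element carries Cochran's Q, its df and p-value.
#' @export
mr_ivw <- function(h, mode = c("fixed", "random"), exposure = NULL) {
  mode <- match.arg(mode)
  v <- h_vectors(h, exposure)
  if (length(v$x) < 2L) abort("IVW needs at least 2 SNPs")
  core <- ivw_core(v$x, v$sx, v$y, v$sy)
  se <- if (mode == "fixed") core$se_fe else
    core$se_fe * sqrt(core$q / (core$j - 1))
  est <- mr_estimate(if (mode == "fixed") "ivw_fe" else "ivw_mre",
                     core$theta, se, core$j,
                     exposure = v$exposure, outcome = v$outcome)
  est$diagnostics <- tibble(
    q = core$q, q_df = core$j - 1L,
    q_pval = pchisq(core$q, core$j - 1L, lower.tail = FALSE)
  )
  est
}

#' MR-Egger regression
#'
#' Weighted linear regression of outcome effects on exposure effects with
#' an intercept, weights `1/se_out^2`, after orienting every SNP so the
#' exposure effect is non-negative. The slope is the pleiotropy-robust
#' causal estimate (valid under the InSIDE assumption); a non-zero
#' intercept indicates directional horizontal pleiotropy. Coefficient SEs
#' carry the multiplicative overdispersion scale `sqrt(Q_egger/(J-2))`,
#' not truncated below 1; p-values are two-sided normal.
#'
#' @inheritParams mr_ivw
#' @return object of class `mr_egger`: list with `slope` and `intercept`
#'   (`mr_estimate`s) plus `q`, `q_df`, `q_pval` for the Egger residual
#'   heterogeneity.
#' @export
mr_egger <- function(h, exposure = NULL) {
  v <- h_vectors(h, exposure)
  j <- length(v$x)
  if (j < 3L) abort("MR-Egger needs at least 3 SNPs")
  flip <- sign(v$x) < 0
  x <- abs(v$x)
  y <- ifelse(flip, -v$y, v$y)
  w <- 1 / v$sy^2
  sw <- sum(w)
  xbar <- sum(w * x) / sw
  ybar <- sum(w * y) / sw
  sxx <- sum(w * (x - xbar)^2)
  slope <- sum(w * (x - xbar) * (y - ybar)) / sxx
  icpt <- ybar - slope * xbar
  resid <- y - icpt - slope * x
  q <- sum(w * resid^2)
  sigma2 <- q / (j - 2)
  se_slope <- sqrt(sigma2 / sxx)
  se_icpt <- sqrt(sigma2 * (1 / sw + xbar^2 / sxx))
  out <- structure(list(
    slope = mr_estimate("egger_slope", slope, se_slope, j,
                        exposure = v$exposure, outcome = v$outcome),
    intercept = mr_estimate("egger_intercept", icpt, se_icpt, j,
                            exposure = v$exposure, outcome = v$outcome),
    q = q, q_df = j - 2L,
    q_pval = pchisq(q, j - 2L, lower.tail = FALSE)
  ), class = "mr_egger")
  out
}

#' @export
print.mr_egger <- function(x, ...) {
  print(x$slope)
  print(x$intercept)
  cat(sprintf("  Q_egger = %.3f (df %d, p = %.3g)\n", x$q, x$q_df, x$q_pval))
  invisible(x)
}

#' @export
tidy.mr_egger <- function(x, ...) {
  dplyr::bind_rows(tidy(x$slope), tidy(x$intercept))
}

#' @export
glance.mr_egger <- function(x, ...) {
  tibble(method = "egger", nsnp = x$slope$n_snp,
         q = x$q, q_df = x$q_df, q_pval = x$q_pval,
         intercept = x$intercept$theta, intercept_pval = x$intercept$pval)
}

# Weighted median of ratios: sorted ratios, cumulative weight midpoints,
# linear interpolation at cumulative weight 0.5.
weighted_median_point <- function(theta, w) {
  o <- order(theta)
  theta <- theta[o]
  w <- w[o] / sum(w)
  s <- cumsum(w) - w / 2
  if (0.5 <= s[1]) return(theta[1])
  n <- length(theta)
  if (0.5 >= s[n]) return(theta[n])
  approx(s, theta, xout = 0.5, ties = "ordered")$y
}

#' Weighted-median estimate
#'
#' The inverse-variance weighted median of the per-SNP Wald ratios:
#' consistent when instruments carrying at least half the total weight are
#' valid, hence robust to up to 50% invalid instruments. The point
#' estimate interpolates linearly in cumulative normalized weight; with
#' equal weights it equals the ordinary median of ratios. The SE comes
#' from a seeded parametric bootstrap that redraws `beta_exp` and
#' `beta_out` from their normal sampling distributions.
#'
#' @inheritParams mr_ivw
#' @param n_boot bootstrap draws for the SE (default 1000, minimum 100).
#' @param seed integer seed for the bootstrap (required).
#' @return an `mr_estimate` with method `weighted_median`.
#' @export
mr_weighted_median <- function(h, n_boot = 1000, seed, exposure = NULL) {
  stopifnot(n_boot >= 100)
  if (missing(seed)) abort("a bootstrap seed is required for reproducibility")
  v <- h_vectors(h, exposure)
  j <- length(v$x)
  if (j < 3L) abort("weighted median needs at least 3 SNPs")
  wr <- wald_ratio(v$x, v$sx, v$y, v$sy)
  w <- 1 / wr$se^2
  point <- weighted_median_point(wr$theta, w)
  set.seed(seed)
  boot <- vapply(seq_len(n_boot), function(b) {
    xb <- rnorm(j, v$x, v$sx)
    yb <- rnorm(j, v$y, v$sy)
    xb[xb == 0] <- .Machine$double.eps  # guard a measure-zero event
    tb <- yb / xb
    wb <- xb^2 / v$sy^2
    weighted_median_point(tb, wb)
  }, numeric(1))
  mr_estimate("weighted_median", point, sd(boot), j,
              exposure = v$exposure, outcome = v$outcome)
}

#' Cochran's Q heterogeneity test
#'
#' Q is the inverse-variance weighted sum of squared deviations of the
#' per-SNP Wald ratios from a reference causal estimate (the IVW estimate
#' by default). Excess Q relative to its chi-square reference signals
#' heterogeneity, i.e. some instruments are invalid. Degrees of freedom
#' are J - 1, or J - 2 when the reference comes from an Egger fit
#' (`df_adjust = 2`).
#'
#' @inheritParams mr_ivw
#' @param theta_ref reference causal effect; default recomputes IVW.
#' @param df_adjust parameters absorbed by the reference (1 for IVW,
#'   2 for Egger).
#' @return one-row tibble: `q`, `df`, `pval`.
#' @export
cochran_q <- function(h, theta_ref = NULL, df_adjust = 1, exposure = NULL) {
  v <- h_vectors(h, exposure)
  j <- length(v$x)
  if (j < 2L) abort("Cochran's Q needs at least 2 SNPs")
  wr <- wald_ratio(v$x, v$sx, v$y, v$sy)
  w <- 1 / wr$se^2
  theta_ref <- theta_ref %||% (sum(w * wr$theta) / sum(w))
  q <- sum(w * (wr$theta - theta_ref)^2)
  df <- j - df_adjust
  tibble(q = q, df = as.integer(df),
         pval = pchisq(q, df, lower.tail = FALSE))
}

#' Leave-one-out IVW analysis
#'
#' Refits the IVW estimate once per omitted SNP and ranks instruments by
#' influence, the absolute shift of the estimate when the SNP is dropped.
#' A dominant instrument or outlier surfaces at the top of the ranking.
#'
#' @inheritParams mr_ivw
#' @param mode IVW mode used for each refit.
#' @return tibble of class `mr_loo`: one row per omitted SNP (`snp`, `b`,
#'   `se`, `ci_low`, `ci_high`, `pval`, `influence`, `rank`), sorted by
#'   the input SNP order; the full-set estimate is in attribute `"full"`.
#' @export
mr_leave_one_out <- function(h, mode = c("fixed", "random"), exposure = NULL) {
  mode <- match.arg(mode)
  v <- h_vectors(h, exposure)
  j <- length(v$x)
  if (j < 3L) abort("leave-one-out needs at least 3 SNPs")
  full <- mr_ivw(h, mode = mode, exposure = exposure)
  rows <- purrr::map(seq_len(j), function(i) {
    hi <- mr_input(v$x[-i], v$sx[-i], v$y[-i], v$sy[-i], snp = v$snp[-i],
                   exposure = v$exposure, outcome = v$outcome)
    e <- mr_ivw(hi, mode = mode)
    tibble(snp = v$snp[i], b = e$theta, se = e$se,
           ci_low = e$ci_low, ci_high = e$ci_high, pval = e$pval)
  })
  out <- dplyr::bind_rows(rows)
  out$influence <- abs(out$b - full$theta)
  out$rank <- rank(-out$influence, ties.method = "first")
  structure(out, full = full, class = c("mr_loo", class(out)))
}

#' Run all univariable estimators on one harmonized set
#'
#' Convenience wrapper returning the tidy estimate table for fixed- and
#' random-effects IVW, MR-Egger (slope and intercept) and the weighted
#' median.
#'
#' @inheritParams mr_weighted_median
#' @return tibble with one row per method in the tidy estimate layout.
#' @export
mr_all_methods <- function(h, n_boot = 1000, seed, exposure = NULL) {
  dplyr::bind_rows(
    tidy(mr_ivw(h, "fixed", exposure = exposure)),
    tidy(mr_ivw(h, "random", exposure = exposure)),
    tidy(mr_egger(h, exposure = exposure)),
    tidy(mr_weighted_median(h, n_boot = n_boot, seed = seed,
                            exposure = exposure))
  )
}
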