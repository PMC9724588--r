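#' Multivariable MR: direct effects of several exposures
#'
#' Weighted multiple linear regression of outcome effects on the K
#' exposure-effect columns without an intercept, weights `1/se_out^2`.
#' Each coefficient is the direct effect of that exposure on the outcome,
#' mutually adjusted for the co-exposures. Coefficient SEs carry the
#' multiplicative overdispersion scale `sqrt(Q_cond/(J-K))`, not truncated
#' below 1, where `Q_cond` is the conditional heterogeneity statistic
#' (weighted residual sum of squares). With a single exposure the fit
#' reduces exactly to random-effects IVW.
#'
#' Exposure columns that are identically zero are dropped with a warning
#' (their estimate is reported as `NA`); genuine collinearity among the
#' remaining columns is a fatal error naming the offending exposures.
#' A per-exposure conditional instrument-strength approximation (mean
#' weighted squared residual of that exposure's effects after projecting
#' out the co-exposures) is reported, with a warning below 10.
#'
#' @param h an `mr_harmonized` tibble with K >= 1 exposures.
#' @param exposures subset/order of exposures to fit (default: all, primary
#'   first).
#' @return object of class `mr_mvmr`: `estimates` (named list of
#'   `mr_estimate`s), `conditional_q` (tibble `q`, `df`, `pval`),
#'   `conditional_f` (named vector), `n_snp`, `n_exposure`.
#' @export
mr_mvmr <- function(h, exposures = NULL) {
  nms <- exposures %||% exposure_names(h)
  k0 <- length(nms)
  x_all <- exposure_matrix(h, nms, "beta")
  sx_all <- exposure_matrix(h, nms, "se")
  y <- h$beta_out
  sy <- h$se_out
  j <- length(y)

  zero_col <- apply(x_all, 2, function(c) all(c == 0))
  if (any(zero_col)) {
    warn(paste0("exposure(s) with all-zero effects dropped from MVMR fit: ",
                paste(nms[zero_col], collapse = ", ")))
  }
  fit_nms <- nms[!zero_col]
  x <- x_all[, !zero_col, drop = FALSE]
  sx <- sx_all[, !zero_col, drop = FALSE]
  k <- ncol(x)
  if (k < 1L) abort("no usable exposure columns")
  if (j <= k + 1L) {
    abort(sprintf("MVMR needs more SNPs than exposures + 1 (J = %d, K = %d)",
                  j, k))
  }
  w <- 1 / sy^2
  xw <- sqrt(w) * x
  qr_x <- qr(xw)
  if (qr_x$rank < k) {
    bad <- fit_nms[qr_x$pivot[(qr_x$rank + 1L):k]]
    abort(paste0("exposure-effect matrix is rank deficient; collinear ",
                 "exposure(s): ", paste(bad, collapse = ", ")))
  }
  xtwx <- crossprod(xw)
  v0 <- solve(xtwx)
  bhat <- drop(v0 %*% crossprod(x, w * y))
  resid <- y - drop(x %*% bhat)
  q_cond <- sum(w * resid^2)
  df <- j - k
  sigma2 <- q_cond / df
  se <- sqrt(diag(v0) * sigma2)

  cond_f <- vapply(seq_len(k), function(i) {
    xi <- x[, i]
    if (k == 1L) {
      r <- xi
    } else {
      wi <- 1 / sx[, i]^2
      z <- x[, -i, drop = FALSE]
      g <- tryCatch(
        solve(crossprod(sqrt(wi) * z), crossprod(z, wi * xi)),
        error = function(e) NULL)
      r <- if (is.null(g)) xi else xi - drop(z %*% g)
    }
    mean(r^2 / sx[, i]^2)
  }, numeric(1))
  names(cond_f) <- fit_nms
  weak <- cond_f < 10
  if (any(weak)) {
    warn(paste0("conditional F < 10 for exposure(s): ",
                paste(fit_nms[weak], collapse = ", "),
                " - possible conditionally weak instruments"))
  }

  outcome <- attr(h, "outcome") %||% "outcome"
  estimates <- setNames(vector("list", k0), nms)
  for (i in seq_len(k0)) {
    nm <- nms[i]
    if (zero_col[i]) {
      estimates[[nm]] <- mr_estimate("mvmr", NA_real_, NA_real_, j,
                                     exposure = nm, outcome = outcome,
                                     adjusted_for = setdiff(nms, nm))
    } else {
      idx <- match(nm, fit_nms)
      estimates[[nm]] <- mr_estimate("mvmr", unname(bhat[idx]),
                                     unname(se[idx]), j,
                                     exposure = nm, outcome = outcome,
                                     adjusted_for = setdiff(nms, nm))
    }
  }

  structure(list(
    estimates = estimates,
    conditional_q = tibble(q = q_cond, df = as.integer(df),
                           pval = pchisq(q_cond, df, lower.tail = FALSE)),
    conditional_f = cond_f,
    n_snp = as.integer(j), n_exposure = as.integer(k0)
  ), class = "mr_mvmr")
}

#' @export
print.mr_mvmr <- function(x, ...) {
  cat(sprintf("<mr_mvmr> %d SNPs, %d exposures\n", x$n_snp, x$n_exposure))
  for (e in x$estimates) print(e)
  cat(sprintf("conditional Q = %.3f (df %d, p = %.3g)\n",
              x$conditional_q$q, x$conditional_q$df, x$conditional_q$pval))
  invisible(x)
}

#' @export
tidy.mr_mvmr <- function(x, ...) {
  dplyr::bind_rows(purrr::map(x$estimates, tidy))
}

#' @export
glance.mr_mvmr <- function(x, ...) {
  tibble(nsnp = x$n_snp, n_exposure = x$n_exposure,
         q_cond = x$conditional_q$q, q_df = x$conditional_q$df,
         q_pval = x$conditional_q$pval,
         min_conditional_f = min(x$conditional_f))
}
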