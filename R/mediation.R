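#' Two-step MR mediation by the product-of-coefficients method
#'
#' Decomposes a total causal effect into the part flowing through a
#' mediator and the rest. Step 1 (`a`) is the univariable MR estimate of
#' exposure on mediator; step 2 (`b`) is the mediator's direct effect on
#' the outcome adjusted for the exposure (from multivariable MR); the
#' indirect effect is `a * b` and the proportion mediated is
#' `a * b / total`. Standard errors are first-order delta-method
#' propagations with the a-b covariance taken as zero (the two estimates
#' come from separate regressions on separate samples):
#' `se(indirect) = sqrt(a^2 se_b^2 + b^2 se_a^2)`. The proportion SE
#' propagates both the indirect and the total variance by default;
#' `total_fixed = TRUE` conditions on the total effect. Confidence
#' intervals are symmetric normal intervals on the computed scale.
#'
#' @param total `mr_estimate` of the exposure's total effect on the outcome.
#' @param a `mr_estimate` of the exposure's effect on the mediator.
#' @param b `mr_estimate` of the mediator's direct effect on the outcome
#'   (adjusted for the exposure).
#' @param total_fixed treat the total effect as fixed in the proportion SE.
#' @return object of class `mr_mediation` with elements `total`, `a`, `b`,
#'   `indirect` (`theta`, `se`, `ci_low`, `ci_high`, `pval`), `proportion`
#'   (same fields, on the proportion scale).
#' @export
#' @examples
#' tot <- mr_estimate("ivw_fe", log(1.19), 0.066, 229)
#' a <- mr_estimate("ivw_fe", 0.05, 0.020, 229, outcome = "BMI")
#' b <- mr_estimate("mvmr", log(1.70), 0.102, 240, exposure = "BMI")
#' mr_mediation(tot, a, b)
mr_mediation <- function(total, a, b, total_fixed = FALSE) {
  if (total$theta == 0) abort("total effect is zero: proportion undefined")
  z <- qnorm(0.975)
  ind <- a$theta * b$theta
  se_ind <- sqrt(a$theta^2 * b$se^2 + b$theta^2 * a$se^2)
  prop <- ind / total$theta
  var_prop <- (b$theta / total$theta)^2 * a$se^2 +
    (a$theta / total$theta)^2 * b$se^2
  if (!total_fixed) {
    var_prop <- var_prop + (ind / total$theta^2)^2 * total$se^2
  }
  se_prop <- sqrt(var_prop)
  band <- function(est, se) {
    list(theta = est, se = se, ci_low = est - z * se, ci_high = est + z * se,
         pval = if (se == 0) NA_real_ else 2 * pnorm(-abs(est) / se))
  }
  structure(list(
    total = total, a = a, b = b,
    indirect = band(ind, se_ind),
    proportion = band(prop, se_prop),
    total_fixed = total_fixed
  ), class = "mr_mediation")
}

#' @export
print.mr_mediation <- function(x, ...) {
  cat(sprintf(
    "<mr_mediation> %s -> %s -> %s\n  total = %.4f, a = %.4f, b = %.4f\n  indirect = %.4f (se %.4f), proportion mediated = %.1f%% [%.1f%%, %.1f%%]\n",
    x$a$exposure, x$b$exposure, x$total$outcome,
    x$total$theta, x$a$theta, x$b$theta,
    x$indirect$theta, x$indirect$se,
    100 * x$proportion$theta, 100 * x$proportion$ci_low,
    100 * x$proportion$ci_high))
  invisible(x)
}

#' @export
tidy.mr_mediation <- function(x, ...) {
  row <- function(path, e) {
    tibble(path = path, estimate = e$theta, se = e$se,
           ci_low = e$ci_low, ci_high = e$ci_high, pval = e$pval)
  }
  dplyr::bind_rows(
    row("total", x$total), row("exposure->mediator (a)", x$a),
    row("mediator->outcome|exposure (b)", x$b),
    row("indirect (a*b)", x$indirect),
    row("proportion mediated", x$proportion)
  )
}

#' @export
glance.mr_mediation <- function(x, ...) {
  tibble(indirect = x$indirect$theta, indirect_se = x$indirect$se,
         proportion = x$proportion$theta, proportion_se = x$proportion$se,
         proportion_ci_low = x$proportion$ci_low,
         proportion_ci_high = x$proportion$ci_high)
}

#' Gate a mediation candidate on the step-1 estimate
#'
#' A candidate proceeds to the product-of-coefficients decomposition only
#' if the exposure-to-mediator estimate is significant (strict inequality
#' at `alpha`); otherwise it is reported as "not a mediator".
#'
#' @param a `mr_estimate` of the exposure on the candidate mediator.
#' @param alpha significance level (default 0.05).
#' @return `TRUE` to proceed, `FALSE` to stop.
#' @export
mediation_gate <- function(a, alpha = 0.05) {
  isTRUE(a$pval < alpha)
}

#' Power of a two-sample MR design with a binary outcome
#'
#' Closed-form normal approximation for the power of an IVW-style MR test
#' of an odds ratio per SD of exposure, with a binary outcome analysed by
#' logistic regression. With case fraction K, the attenuated
#' log-odds-scale association is `b = K * (OR / (1 + K*(OR - 1)) - 1)`,
#' its variance is `v = (K*(1-K) - b^2) / (N * R2)` where R2 is the
#' variance of the exposure explained by the instruments, and power is
#' `pnorm(|b|/sqrt(v) - z_{1-alpha/2})` (the one-tail-of-two-sided
#' approximation, so the null OR = 1 yields alpha/2).
#'
#' @param n_total total outcome sample size (cases + controls).
#' @param case_fraction cases / n_total, in (0, 1).
#' @param odds_ratio hypothesized OR per SD of exposure.
#' @param r2 instrument variance explained, in (0, 1).
#' @param alpha two-sided type-1 error rate (default 0.05).
#' @return one-row tibble echoing the design plus the computed `power`.
#' @export
#' @examples
#' mr_power_binary(213746, 3283 / 213746, 1.36, 0.0476)
mr_power_binary <- function(n_total, case_fraction, odds_ratio, r2,
                            alpha = 0.05) {
  stopifnot(n_total > 0)
  if (case_fraction <= 0 || case_fraction >= 1) {
    abort("case_fraction must lie in (0, 1)")
  }
  if (r2 <= 0 || r2 >= 1) abort("r2 must lie in (0, 1)")
  if (alpha <= 0 || alpha >= 1) abort("alpha must lie in (0, 1)")
  if (odds_ratio <= 0) abort("odds_ratio must be positive")
  k <- case_fraction
  b <- k * (odds_ratio / (1 + k * (odds_ratio - 1)) - 1)
  v <- (k * (1 - k) - b^2) / (n_total * r2)
  power <- pnorm(abs(b) / sqrt(v) - qnorm(1 - alpha / 2))
  tibble(n_total = n_total, case_fraction = k, odds_ratio = odds_ratio,
         r2 = r2, alpha = alpha, power = power)
}
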