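#' Forest plot of MR estimates
#'
#' Draws odds ratios with 95% confidence intervals for a tidy estimate
#' table (the layout produced by [tidy()] on any estimator, or by
#' [mr_all_methods()]). Rows are labelled exposure / method; the vertical
#' line marks the null OR = 1 and the x axis is log-scaled.
#'
#' @param estimates tidy estimate tibble (`or`, `or_ci_low`, `or_ci_high`,
#'   `method`, `exposure`, ...).
#' @return a ggplot object.
#' @export
plot_forest <- function(estimates) {
  df <- dplyr::mutate(
    estimates,
    label = paste0(.data$exposure, " [", .data$method, "]",
                   ifelse(.data$adjusted_for == "", "",
                          paste0(" adj. ", .data$adjusted_for)))
  )
  df$label <- factor(df$label, levels = rev(unique(df$label)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$or, y = .data$label)) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$or_ci_low, xmax = .data$or_ci_high),
      height = 0.2) +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Odds ratio per SD (95% CI)", y = NULL) +
    ggplot2::theme_minimal()
}

#' @describeIn plot_forest autoplot method for leave-one-out results:
#'   the IVW estimate after omitting each SNP, with the full-set estimate
#'   as a reference line.
#' @param object an `mr_loo` tibble from [mr_leave_one_out()].
#' @param ... unused.
#' @export
autoplot.mr_loo <- function(object, ...) {
  full <- attr(object, "full")
  df <- as_tibble(object)
  df$snp <- factor(df$snp, levels = rev(df$snp))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$b, y = .data$snp)) +
    ggplot2::geom_vline(xintercept = full$theta, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_vline(xintercept = 0, colour = "grey80") +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$ci_low, xmax = .data$ci_high),
      height = 0.2) +
    ggplot2::geom_point(size = 1.5) +
    ggplot2::labs(x = "IVW estimate omitting each SNP (log-odds per SD)",
                  y = NULL) +
    ggplot2::theme_minimal()
}

#' Scatter plot of a harmonized set with fitted MR slopes
#'
#' Per-SNP outcome effects against exposure effects with the IVW (through
#' the origin) and MR-Egger (free intercept) fits overlaid.
#'
#' @param h an `mr_harmonized` tibble.
#' @param exposure which exposure to plot (default primary).
#' @return a ggplot object.
#' @export
plot_mr_scatter <- function(h, exposure = NULL) {
  v <- h_vectors(h, exposure)
  ivw <- mr_ivw(h, "fixed", exposure = exposure)
  eg <- mr_egger(h, exposure = exposure)
  flip <- sign(v$x) < 0
  df <- tibble(x = abs(v$x), y = ifelse(flip, -v$y, v$y),
               sy = v$sy, sx = v$sx)
  lines <- tibble(
    method = c("IVW", "MR-Egger"),
    intercept = c(0, eg$intercept$theta),
    slope = c(ivw$theta, eg$slope$theta)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$y - .data$sy, ymax = .data$y + .data$sy),
      colour = "grey70", width = 0) +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$x - .data$sx, xmax = .data$x + .data$sx),
      colour = "grey70", height = 0) +
    ggplot2::geom_point(size = 1.5) +
    ggplot2::geom_abline(
      data = lines,
      ggplot2::aes(intercept = .data$intercept, slope = .data$slope,
                   colour = .data$method)) +
    ggplot2::labs(x = paste0("SNP effect on ", v$exposure),
                  y = paste0("SNP effect on ", v$outcome),
                  colour = NULL) +
    ggplot2::theme_minimal()
}
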