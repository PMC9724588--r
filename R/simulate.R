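#' Configuration for the synthetic two-sample GWAS generator
#'
#' Defaults emulate the statistical structure of the study design the
#' package targets: a continuous serum biomarker measured in a large
#' biobank exposure GWAS (N = 361,194), a rare binary kidney-disease
#' outcome from a separate biobank (N = 213,746 with case fraction
#' 3283/213746), roughly 234 independent instruments explaining about
#' 9.6% of exposure variance, and a true odds ratio of about 1.19 per SD.
#' Effects are drawn at the summary level: no individual genotypes and no
#' LD between instruments (they are post-clumping by construction).
#'
#' Directional pleiotropy and planted outlier offsets are defined relative
#' to the exposure-increasing allele (they enter the outcome as
#' `sign(gamma_j) * offset`), the standard simulation convention that
#' makes the MR-Egger intercept estimand equal `pleiotropy_mean` after
#' the usual orientation of SNPs to positive exposure effects.
#'
#' @param n_snp number of instruments (>= 4).
#' @param n_exposure_sample,n_outcome_sample,n_mediator_sample GWAS sample
#'   sizes.
#' @param theta_true causal effect of exposure on outcome
#'   (log-odds per SD for a binary outcome).
#' @param target_r2 exposure variance explained by all instruments jointly;
#'   sets `gamma_sd` when the latter is `NULL`.
#' @param gamma_sd SD of true per-SNP exposure effects; overrides
#'   `target_r2` when given.
#' @param pleiotropy_mean,pleiotropy_sd mean and SD of per-SNP direct
#'   (pleiotropic) outcome effects; mean 0 with positive SD is balanced
#'   pleiotropy, nonzero mean is directional. Independent of instrument
#'   strength (InSIDE holds).
#' @param n_outliers number of planted outlier instruments.
#' @param outlier_magnitude outlier offset in units of the SNP's outcome SE.
#' @param case_fraction outcome case fraction in (0, 1); `NULL` for a
#'   continuous outcome.
#' @param a_true,b_true,c_true mediation path coefficients
#'   (exposure -> mediator, mediator -> outcome, direct exposure -> outcome);
#'   used by [simulate_mediation()]. `c_true = NULL` derives the direct
#'   effect as `theta_true - a_true * b_true` so the total matches
#'   `theta_true`.
#' @param n_snp_mediator extra mediator-specific instruments (no exposure
#'   effect) so multivariable fits are identified; default `n_snp / 2`.
#' @param swap_fraction fraction of outcome/mediator rows emitted with
#'   swapped allele labels (and negated beta, mirrored eaf) to exercise
#'   harmonization.
#' @param n_palindromic count of SNPs emitted with A/T alleles so
#'   harmonization has palindromes to drop.
#' @param seed integer seed (required; every draw depends on it).
#' @return a `sim_config` list, validated.
#' @export
sim_config <- function(n_snp = 234,
                       n_exposure_sample = 361194,
                       n_outcome_sample = 213746,
                       n_mediator_sample = 681275,
                       theta_true = log(1.19),
                       target_r2 = 0.0959,
                       gamma_sd = NULL,
                       pleiotropy_mean = 0,
                       pleiotropy_sd = 0,
                       n_outliers = 0,
                       outlier_magnitude = 10,
                       case_fraction = 3283 / 213746,
                       a_true = 0.05,
                       b_true = log(1.70),
                       c_true = NULL,
                       n_snp_mediator = NULL,
                       swap_fraction = 0,
                       n_palindromic = 0,
                       seed) {
  if (missing(seed)) abort("sim_config requires a seed")
  stopifnot(n_snp >= 4, n_exposure_sample > 0, n_outcome_sample > 0,
            n_mediator_sample > 0, n_outliers >= 0, n_outliers <= n_snp,
            swap_fraction >= 0, swap_fraction <= 1,
            n_palindromic >= 0, n_palindromic <= n_snp)
  if (!is.null(case_fraction)) {
    stopifnot(case_fraction > 0, case_fraction < 1)
  }
  # E[2p(1-p)] = 0.365 for p ~ U(0.05, 0.95); calibrates gamma_sd so the
  # expected summed variance explained matches target_r2.
  gamma_sd <- gamma_sd %||% sqrt(target_r2 / (n_snp * 0.365))
  c_true <- c_true %||% (theta_true - a_true * b_true)
  structure(list(
    n_snp = as.integer(n_snp),
    n_exposure_sample = n_exposure_sample,
    n_outcome_sample = n_outcome_sample,
    n_mediator_sample = n_mediator_sample,
    theta_true = theta_true, target_r2 = target_r2, gamma_sd = gamma_sd,
    pleiotropy_mean = pleiotropy_mean, pleiotropy_sd = pleiotropy_sd,
    n_outliers = as.integer(n_outliers),
    outlier_magnitude = outlier_magnitude,
    case_fraction = case_fraction,
    a_true = a_true, b_true = b_true, c_true = c_true,
    n_snp_mediator = as.integer(n_snp_mediator %||% ceiling(n_snp / 2)),
    swap_fraction = swap_fraction,
    n_palindromic = as.integer(n_palindromic),
    seed = as.integer(seed)
  ), class = "sim_config")
}

two_sided_p <- function(beta, se) {
  pmax(2 * pnorm(-abs(beta / se)), 1e-300)
}

# Emit a canonical GWAS table, optionally with swapped allele labels
# (negated beta, mirrored eaf) and planted palindromic allele pairs.
emit_table <- function(snp, chrom, pos, eaf, beta, se, n,
                       pal_idx = integer(), swap_idx = integer()) {
  ea <- rep("A", length(snp)); oa <- rep("G", length(snp))
  oa[pal_idx] <- "T"
  swap_idx <- setdiff(swap_idx, pal_idx)
  tmp <- ea[swap_idx]; ea[swap_idx] <- oa[swap_idx]; oa[swap_idx] <- tmp
  beta[swap_idx] <- -beta[swap_idx]
  eaf[swap_idx] <- 1 - eaf[swap_idx]
  tibble(snp = snp, chrom = chrom, pos = pos,
         effect_allele = ea, other_allele = oa, eaf = eaf,
         beta = beta, se = se, pval = two_sided_p(beta, se),
         n = rep(as.integer(round(n)), length(snp)))
}

#' Simulate a two-sample MR study with known ground truth
#'
#' Draws summary statistics directly at the summary level. Per SNP j:
#' `eaf_j ~ U(0.05, 0.95)`; true exposure effect
#' `gamma_j ~ N(0, gamma_sd^2)`; exposure SE
#' `1/sqrt(2 eaf (1-eaf) N_exp)`; observed exposure beta
#' `~ N(gamma_j, se_x^2)`. The true outcome association is
#' `theta_true * gamma_j` plus a pleiotropic offset
#' `sign(gamma_j) * alpha_j` with `alpha_j ~ N(pleiotropy_mean,
#' pleiotropy_sd^2)` drawn independently of `gamma_j` (InSIDE holds),
#' plus `sign(gamma_j) * outlier_magnitude * se_y` for planted outliers.
#' The binary-outcome SE is `1/sqrt(2 eaf (1-eaf) N_out K (1-K))`.
#' P-values are two-sided normal. Instruments sit on chromosomes 1-22 at
#' positions spaced 3 Mb, i.e. mutually independent under a 1 Mb clump
#' window.
#'
#' @param config a [sim_config()].
#' @return object of class `mr_simulation`: `exposure` and `outcome`
#'   tables (canonical GWAS columns), and `truth` — the config plus the
#'   realized `gamma`, `alpha`, `outlier_ids` and SNP ids.
#' @export
simulate_two_sample <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  j <- config$n_snp
  snp <- sprintf("rs%06d", seq_len(j))
  chrom <- as.character(((seq_len(j) - 1L) %% 22L) + 1L)
  pos <- 1e6 + 3e6 * ((seq_len(j) - 1L) %/% 22L)

  eaf <- runif(j, 0.05, 0.95)
  gamma <- rnorm(j, 0, config$gamma_sd)
  het <- 2 * eaf * (1 - eaf)
  se_x <- 1 / sqrt(het * config$n_exposure_sample)
  beta_x <- rnorm(j, gamma, se_x)

  k <- config$case_fraction
  se_y <- if (is.null(k)) {
    1 / sqrt(het * config$n_outcome_sample)
  } else {
    1 / sqrt(het * config$n_outcome_sample * k * (1 - k))
  }
  alpha <- if (config$pleiotropy_sd > 0 || config$pleiotropy_mean != 0) {
    rnorm(j, config$pleiotropy_mean, config$pleiotropy_sd)
  } else {
    rep(0, j)
  }
  outlier_idx <- if (config$n_outliers > 0) {
    sort(sample.int(j, config$n_outliers))
  } else integer()
  gamma_out <- config$theta_true * gamma + sign(gamma) * alpha
  gamma_out[outlier_idx] <- gamma_out[outlier_idx] +
    sign(gamma[outlier_idx]) * config$outlier_magnitude * se_y[outlier_idx]
  beta_y <- rnorm(j, gamma_out, se_y)

  pal_idx <- seq_len(config$n_palindromic)
  swap_idx <- which(runif(j) < config$swap_fraction)

  exposure <- emit_table(snp, chrom, pos, eaf, beta_x, se_x,
                         config$n_exposure_sample, pal_idx = pal_idx)
  outcome <- emit_table(snp, chrom, pos, eaf, beta_y, se_y,
                        config$n_outcome_sample, pal_idx = pal_idx,
                        swap_idx = swap_idx)

  structure(list(
    exposure = exposure, outcome = outcome, mediator = NULL,
    truth = list(config = config, snp = snp, gamma = gamma, alpha = alpha,
                 outlier_ids = snp[outlier_idx],
                 swapped_ids = snp[swap_idx],
                 palindromic_ids = snp[pal_idx])
  ), class = "mr_simulation")
}

#' Simulate a mediation-structured two-sample study
#'
#' Adds a mediator pathway to [simulate_two_sample()]: the mediator's true
#' association per exposure instrument is `a_true * gamma_j`, and
#' `n_snp_mediator` extra mediator-specific instruments (no exposure
#' effect, mediator effects drawn `N(0, gamma_sd^2)`) are appended so a
#' joint multivariable fit of exposure and mediator is identified. The
#' outcome truth is `c_true * gamma_j + b_true * m_j` plus pleiotropy, so
#' the exposure's total effect equals `c_true + a_true * b_true` by
#' construction.
#'
#' @param config a [sim_config()] with mediation fields set.
#' @return an `mr_simulation` with an additional `mediator` table; `truth`
#'   gains `delta` (mediator-specific effects), `m_truth` and the path
#'   coefficients.
#' @export
simulate_mediation <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_snp_mediator < 1L) {
    abort("mediation simulation needs mediator-specific instruments (n_snp_mediator >= 1)")
  }
  set.seed(config$seed)
  j_e <- config$n_snp
  j_m <- config$n_snp_mediator
  j <- j_e + j_m
  snp <- sprintf("rs%06d", seq_len(j))
  chrom <- as.character(((seq_len(j) - 1L) %% 22L) + 1L)
  pos <- 1e6 + 3e6 * ((seq_len(j) - 1L) %/% 22L)

  eaf <- runif(j, 0.05, 0.95)
  gamma <- c(rnorm(j_e, 0, config$gamma_sd), rep(0, j_m))
  delta <- c(rep(0, j_e), rnorm(j_m, 0, config$gamma_sd))
  het <- 2 * eaf * (1 - eaf)

  se_x <- 1 / sqrt(het * config$n_exposure_sample)
  beta_x <- rnorm(j, gamma, se_x)

  m_truth <- config$a_true * gamma + delta
  se_m <- 1 / sqrt(het * config$n_mediator_sample)
  beta_m <- rnorm(j, m_truth, se_m)

  k <- config$case_fraction
  se_y <- if (is.null(k)) {
    1 / sqrt(het * config$n_outcome_sample)
  } else {
    1 / sqrt(het * config$n_outcome_sample * k * (1 - k))
  }
  alpha <- if (config$pleiotropy_sd > 0 || config$pleiotropy_mean != 0) {
    rnorm(j, config$pleiotropy_mean, config$pleiotropy_sd)
  } else {
    rep(0, j)
  }
  gamma_out <- config$c_true * gamma + config$b_true * m_truth +
    sign(gamma) * alpha
  beta_y <- rnorm(j, gamma_out, se_y)

  pal_idx <- seq_len(config$n_palindromic)
  swap_idx <- which(runif(j) < config$swap_fraction)

  structure(list(
    exposure = emit_table(snp, chrom, pos, eaf, beta_x, se_x,
                          config$n_exposure_sample, pal_idx = pal_idx),
    outcome = emit_table(snp, chrom, pos, eaf, beta_y, se_y,
                         config$n_outcome_sample, pal_idx = pal_idx,
                         swap_idx = swap_idx),
    mediator = emit_table(snp, chrom, pos, eaf, beta_m, se_m,
                          config$n_mediator_sample, pal_idx = pal_idx,
                          swap_idx = swap_idx),
    truth = list(config = config, snp = snp, gamma = gamma, delta = delta,
                 m_truth = m_truth, alpha = alpha,
                 a_true = config$a_true, b_true = config$b_true,
                 c_true = config$c_true,
                 total_true = config$c_true + config$a_true * config$b_true,
                 exposure_instrument_ids = snp[seq_len(j_e)],
                 mediator_instrument_ids = snp[j_e + seq_len(j_m)],
                 outlier_ids = character(),
                 swapped_ids = snp[swap_idx],
                 palindromic_ids = snp[pal_idx])
  ), class = "mr_simulation")
}

#' Write a simulated study to disk
#'
#' Writes the exposure/outcome (and mediator, if present) tables in the
#' delimited GWAS dialect that [read_gwas_table()] reads, plus the ground
#' truth as JSON.
#'
#' @param study an `mr_simulation`.
#' @param dir output directory (created if needed).
#' @param column_map dialect used for the table headers.
#' @return named character vector of written paths, invisibly.
#' @export
write_simulation <- function(study, dir, column_map = gwas_columns()) {
  stopifnot(inherits(study, "mr_simulation"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(exposure = file.path(dir, "exposure.tsv"),
             outcome = file.path(dir, "outcome.tsv"))
  write_gwas_table(study$exposure, paths[["exposure"]], column_map)
  write_gwas_table(study$outcome, paths[["outcome"]], column_map)
  if (!is.null(study$mediator)) {
    paths <- c(paths, mediator = file.path(dir, "mediator.tsv"))
    write_gwas_table(study$mediator, paths[["mediator"]], column_map)
  }
  truth <- study$truth
  truth$config <- unclass(truth$config)
  truth_path <- file.path(dir, "truth.json")
  jsonlite::write_json(truth, truth_path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  paths <- c(paths, truth = truth_path)
  invisible(paths)
}
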