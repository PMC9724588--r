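#' Build a pipeline configuration
#'
#' Collects every input and threshold the end-to-end workflow needs. Trait
#' tables may be given as in-memory tibbles (canonical columns) or file
#' paths readable by [read_gwas_table()].
#'
#' @param exposures named list; each element a list with `table` (tibble or
#'   path) and optionally `p_threshold` (default 5e-8, relax per exposure
#'   for traits with few genome-wide hits).
#' @param outcome list with `table`, and for power calculation `n_total`
#'   and `case_fraction`; optionally `name`.
#' @param confounders named list like `exposures`; used as co-exposures in
#'   multivariable MR and as mediation candidates.
#' @param mediators names of `confounders` to test as mediators (default:
#'   all).
#' @param ld LD table (tibble or path) for clumping and proxy lookup.
#' @param clump_r2,clump_window_bp clumping thresholds (defaults 0.001 and
#'   1 Mb).
#' @param outcome_sig_threshold drop instruments associated with the
#'   outcome below this p (default 5e-8).
#' @param ivw_gate_alpha IVW significance gate for proceeding to
#'   multivariable MR and mediation (default 0.05).
#' @param presso_alpha,mediation_alpha test levels (defaults 0.05).
#' @param n_boot weighted-median bootstrap draws.
#' @param n_sim MR-PRESSO simulation draws.
#' @param power_or,power_r2 overrides for the power calculation; defaults
#'   use the outlier-corrected IVW odds ratio and the post-removal
#'   instrument R-squared.
#' @param seed integer seed driving every stochastic stage (required).
#' @param out_dir optional directory: when set, [run_pipeline()] writes the
#'   report and tidy tables there.
#' @return validated `pipeline_config` list.
#' @export
pipeline_config <- function(exposures, outcome, confounders = list(),
                            mediators = NULL, ld = NULL,
                            clump_r2 = 0.001, clump_window_bp = 1e6,
                            outcome_sig_threshold = 5e-8,
                            ivw_gate_alpha = 0.05, presso_alpha = 0.05,
                            mediation_alpha = 0.05,
                            n_boot = 1000, n_sim = 1000,
                            power_or = NULL, power_r2 = NULL,
                            seed, out_dir = NULL) {
  if (missing(seed)) abort("pipeline_config requires a seed")
  if (is.null(names(exposures)) || any(names(exposures) == "")) {
    abort("exposures must be a named list")
  }
  if (length(confounders) &&
      (is.null(names(confounders)) || any(names(confounders) == ""))) {
    abort("confounders must be a named list")
  }
  mediators <- mediators %||% names(confounders)
  bad <- setdiff(mediators, names(confounders))
  if (length(bad)) {
    abort(paste0("mediator(s) not among confounders: ",
                 paste(bad, collapse = ", ")))
  }
  structure(list(
    exposures = exposures, outcome = outcome, confounders = confounders,
    mediators = mediators, ld = ld,
    clump_r2 = clump_r2, clump_window_bp = clump_window_bp,
    outcome_sig_threshold = outcome_sig_threshold,
    ivw_gate_alpha = ivw_gate_alpha, presso_alpha = presso_alpha,
    mediation_alpha = mediation_alpha,
    n_boot = n_boot, n_sim = n_sim,
    power_or = power_or, power_r2 = power_r2,
    seed = as.integer(seed), out_dir = out_dir
  ), class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' The YAML mirrors the arguments of [pipeline_config()]; trait `table`
#' and `ld` entries are file paths, resolved relative to the config file's
#' directory.
#'
#' @param path path to the YAML config.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  fix_path <- function(p) {
    if (is.null(p) || file.exists(p)) p else file.path(base, p)
  }
  fix_traits <- function(traits) {
    lapply(traits, function(t) {
      t$table <- fix_path(t$table)
      t
    })
  }
  raw$exposures <- fix_traits(raw$exposures)
  if (!is.null(raw$confounders)) raw$confounders <- fix_traits(raw$confounders)
  if (!is.null(raw$outcome$table)) raw$outcome$table <- fix_path(raw$outcome$table)
  if (!is.null(raw$ld)) raw$ld <- fix_path(raw$ld)
  do.call(pipeline_config, raw)
}

resolve_table <- function(x) {
  if (is.character(x)) read_gwas_table(x) else as_tibble(x)
}

resolve_ld <- function(x) {
  if (is.null(x)) return(NULL)
  if (is.character(x)) read_ld_table(x) else as_tibble(x)
}

config_hash <- function(config) {
  config <- unclass(config)
  config$out_dir <- NULL  # where output lands is not scientific content
  plain <- rapply(config, function(x) {
    if (is.data.frame(x)) as.list(x) else x
  }, classes = "ANY", how = "replace")
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(plain, tmp, auto_unbox = TRUE, digits = NA,
                       null = "null", force = TRUE)
  unname(tools::md5sum(tmp))
}

# Selected + clumped instrument set for one trait spec.
prepare_instruments <- function(spec, ld, config) {
  tbl <- resolve_table(spec$table)
  sel <- select_instruments(tbl, spec$p_threshold %||% 5e-8)
  clump_instruments(sel, ld = ld, r2_max = config$clump_r2,
                    window_bp = config$clump_window_bp)
}

#' Run the end-to-end MR workflow
#'
#' Executes, per exposure: instrument selection, LD clumping, allele
#' harmonization against the outcome, univariable MR (fixed-effects IVW as
#' the primary estimate; MR-Egger and the weighted median as complementary
#' estimators), Cochran's Q (adding multiplicative-random-effects IVW when
#' heterogeneity is significant), leave-one-out influence ranking, and the
#' MR-PRESSO global/outlier/distortion battery with an outlier-corrected
#' estimate. Exposures passing the IVW significance gate proceed to
#' multivariable MR against the configured confounders and to two-step
#' mediation per configured mediator (gated on the significance of the
#' exposure-to-mediator path); a binary-outcome power calculation closes
#' the report. All randomness derives from the single config seed, so a
#' rerun with the same config reproduces the report byte for byte. A
#' failing stage is caught and recorded; remaining exposures still run.
#'
#' @param config a [pipeline_config()].
#' @return an `mr_report` (nested list; see [write_report()]). When
#'   `config$out_dir` is set the report and tidy tables are also written
#'   there.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  ld <- resolve_ld(config$ld)
  outcome_tbl <- resolve_table(config$outcome$table)
  outcome_name <- config$outcome$name %||% "outcome"
  seed <- config$seed

  report <- list(provenance = list(
    package = "mrpipe",
    version = as.character(utils::packageVersion("mrpipe")),
    seed = seed,
    config_hash = config_hash(config)
  ))

  exposure_results <- list()
  gated <- character()
  for (nm in names(config$exposures)) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch({
      instr <- prepare_instruments(config$exposures[[nm]], ld, config)
      exposures_in <- setNames(list(instr), nm)
      h <- mr_harmonize(exposures_in, outcome_tbl,
                        outcome_sig_threshold = config$outcome_sig_threshold,
                        ld = ld, outcome_name = outcome_name)
      strength_in <- tibble(snp = h$snp, eaf = h$eaf,
                            beta = h[[paste0("beta_", nm)]],
                            se = h[[paste0("se_", nm)]])
      strength <- suppressWarnings(strength_summary(strength_in))
      ivw <- mr_ivw(h, "fixed")
      het <- ivw$diagnostics
      egger <- mr_egger(h)
      wm <- mr_weighted_median(h, n_boot = config$n_boot, seed = seed + 1L)
      estimates <- dplyr::bind_rows(tidy(ivw), tidy(egger), tidy(wm))
      if (het$q_pval < 0.05) {
        estimates <- dplyr::bind_rows(estimates, tidy(mr_ivw(h, "random")))
      }
      loo <- mr_leave_one_out(h)
      presso <- if (nrow(h) >= 4) {
        mr_presso(h, n_sim = config$n_sim, seed = seed + 2L,
                  alpha = config$presso_alpha)
      } else NULL
      if (!is.null(presso) && length(presso$outlier_ids)) {
        estimates <- dplyr::bind_rows(estimates, tidy(presso$corrected))
      }
      gate_pass <- ivw$pval < config$ivw_gate_alpha
      if (gate_pass) gated <- c(gated, nm)
      list(
        status = if (gate_pass) "significant" else "gated-out",
        n_input = nrow(resolve_table(config$exposures[[nm]]$table)),
        n_selected = nrow(instr),
        n_harmonized = nrow(h),
        exclusions = exclusions(h),
        strength = strength,
        estimates = estimates,
        heterogeneity = tibble(q = het$q, df = het$q_df, pval = het$q_pval),
        egger_intercept = tidy(egger$intercept),
        loo = as_tibble(loo),
        presso = if (is.null(presso)) NULL else list(
          summary = glance(presso),
          per_snp = presso$per_snp,
          outlier_ids = presso$outlier_ids
        ),
        harmonized = h,
        ivw = ivw,
        corrected = if (!is.null(presso)) presso$corrected else ivw
      )
    }, error = function(e) {
      list(status = paste0("failed: ", conditionMessage(e)))
    })
    message(sprintf("[mrpipe] exposure %s: %s (%.2fs)", nm, res$status,
                    proc.time()[["elapsed"]] - t0))
    exposure_results[[nm]] <- res
  }
  report$exposures <- exposure_results

  # Multivariable MR: gated exposures against all confounders, instrument
  # union across the included traits.
  mvmr_results <- list()
  mediation_results <- list()
  if (length(gated) && length(config$confounders)) {
    conf_full <- lapply(config$confounders, function(s) resolve_table(s$table))
    conf_instr <- lapply(config$confounders, function(s) {
      tryCatch(prepare_instruments(s, ld, config), error = function(e) NULL)
    })
    for (nm in gated) {
      exp_full <- resolve_table(config$exposures[[nm]]$table)
      res <- tryCatch({
        exp_instr_ids <- exposure_results[[nm]]$harmonized$snp
        union_ids <- unique(c(exp_instr_ids,
                              unlist(lapply(conf_instr, function(x) x$snp))))
        prim <- exp_full[exp_full$snp %in% union_ids, , drop = FALSE]
        exposures_in <- c(setNames(list(prim), nm), conf_full)
        hm <- mr_harmonize(exposures_in, outcome_tbl,
                           outcome_sig_threshold = config$outcome_sig_threshold,
                           ld = ld, outcome_name = outcome_name)
        fit <- mr_mvmr(hm)
        list(estimates = tidy(fit), summary = glance(fit),
             conditional_f = as.list(fit$conditional_f))
      }, error = function(e) list(status = paste0("failed: ", conditionMessage(e))))
      mvmr_results[[nm]] <- res

      for (med in config$mediators) {
        key <- paste0(nm, "->", med)
        mres <- tryCatch({
          h_exp <- exposure_results[[nm]]$harmonized
          total <- exposure_results[[nm]]$ivw
          exp_instr <- exp_full[exp_full$snp %in% h_exp$snp, , drop = FALSE]
          h_a <- mr_harmonize(setNames(list(exp_instr), nm),
                              conf_full[[med]],
                              outcome_sig_threshold = 0,
                              ld = ld, outcome_name = med)
          a <- mr_ivw(h_a, "fixed")
          if (!mediation_gate(a, config$mediation_alpha)) {
            list(status = "not a mediator",
                 step1 = tidy(a), gate_pval = a$pval)
          } else {
            med_instr <- conf_instr[[med]]
            pair_ids <- unique(c(h_exp$snp,
                                 if (!is.null(med_instr)) med_instr$snp))
            prim2 <- exp_full[exp_full$snp %in% pair_ids, , drop = FALSE]
            h_b <- mr_harmonize(c(setNames(list(prim2), nm),
                                  setNames(list(conf_full[[med]]), med)),
                                outcome_tbl,
                                outcome_sig_threshold = config$outcome_sig_threshold,
                                ld = ld, outcome_name = outcome_name)
            fit_b <- mr_mvmr(h_b)
            b <- fit_b$estimates[[med]]
            m <- mr_mediation(total, a, b)
            list(status = "mediator", table = tidy(m), summary = glance(m))
          }
        }, error = function(e) list(status = paste0("failed: ", conditionMessage(e))))
        mediation_results[[key]] <- mres
      }
    }
  }
  report$mvmr <- mvmr_results
  report$mediation <- mediation_results

  # Power: defaults to the outlier-corrected estimate and the post-removal
  # instrument strength of the first gated (or first) exposure.
  power <- tryCatch({
    nm <- if (length(gated)) gated[1] else names(config$exposures)[1]
    er <- exposure_results[[nm]]
    if (is.null(er$corrected)) abort("no estimate available for power")
    or_use <- config$power_or %||% er$corrected$or
    r2_use <- config$power_r2 %||% {
      h <- er$harmonized
      keep <- !(h$snp %in% (er$presso$outlier_ids %||% character()))
      sum(variance_explained(h$eaf[keep], h[[paste0("beta_", nm)]][keep]),
          na.rm = TRUE)
    }
    n_total <- config$outcome$n_total %||% max(outcome_tbl$n, na.rm = TRUE)
    kf <- config$outcome$case_fraction
    if (is.null(kf)) abort("outcome case_fraction not configured")
    mr_power_binary(n_total, kf, or_use, r2_use)
  }, error = function(e) tibble(error = conditionMessage(e)))
  report$power <- power

  report <- structure(report, class = "mr_report")
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

#' @export
print.mr_report <- function(x, ...) {
  cat(sprintf("<mr_report> seed %d, config %s\n",
              x$provenance$seed, x$provenance$config_hash))
  for (nm in names(x$exposures)) {
    e <- x$exposures[[nm]]
    cat(sprintf("  %s: %s", nm, e$status))
    if (!is.null(e$estimates)) {
      ivw <- e$estimates[e$estimates$method == "ivw_fe", ]
      cat(sprintf(" | IVW OR %.3f [%.3f, %.3f] p=%.3g (J=%d)",
                  ivw$or, ivw$or_ci_low, ivw$or_ci_high, ivw$pval, ivw$nsnp))
    }
    cat("\n")
  }
  invisible(x)
}

# Strip heavy / non-serializable members before JSON.
report_for_json <- function(report) {
  out <- unclass(report)
  out$exposures <- lapply(out$exposures, function(e) {
    e$harmonized <- NULL
    e$ivw <- NULL
    e$corrected <- NULL
    e
  })
  out
}

#' Write a pipeline report to disk
#'
#' Writes `report.json` (the full structured report), `estimates.tsv`
#' (the combined tidy estimate table across exposures and methods),
#' `exclusions.tsv`, and `leave_one_out.tsv`. Output is deterministic:
#' identical config + seed give byte-identical files.
#'
#' @param report an `mr_report`.
#' @param dir output directory (created if needed).
#' @return named vector of written paths, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(report = file.path(dir, "report.json"))
  jsonlite::write_json(report_for_json(report), paths[["report"]],
                       auto_unbox = TRUE, digits = NA, null = "null",
                       dataframe = "rows", force = TRUE)
  grab <- function(field) {
    dplyr::bind_rows(lapply(names(report$exposures), function(nm) {
      tb <- report$exposures[[nm]][[field]]
      if (is.null(tb) || !nrow(tb)) return(NULL)
      dplyr::bind_cols(tibble(exposure_set = nm), as_tibble(tb))
    }))
  }
  est <- grab("estimates")
  if (!is.null(est) && nrow(est)) {
    paths <- c(paths, estimates = file.path(dir, "estimates.tsv"))
    readr::write_tsv(est, paths[["estimates"]], progress = FALSE)
  }
  exc <- grab("exclusions")
  if (!is.null(exc) && nrow(exc)) {
    paths <- c(paths, exclusions = file.path(dir, "exclusions.tsv"))
    readr::write_tsv(exc, paths[["exclusions"]], progress = FALSE)
  }
  loo <- grab("loo")
  if (!is.null(loo) && nrow(loo)) {
    paths <- c(paths, loo = file.path(dir, "leave_one_out.tsv"))
    readr::write_tsv(loo, paths[["loo"]], progress = FALSE)
  }
  invisible(paths)
}
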