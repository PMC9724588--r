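make_pair <- function(n = 5) {
  exp <- tiny_gwas(n, beta = 0.1, pval = 1e-9)
  out <- exp
  out$beta <- 0.02
  out$se <- 0.01
  out$pval <- 0.05
  list(exp = exp, out = out)
}

test_that("swapped outcome allele labels flip the outcome beta", {
  p <- make_pair(4)
  p$out$effect_allele[1] <- "G"
  p$out$other_allele[1] <- "A"
  p$out$beta[1] <- 0.1
  p$out$eaf[1] <- 0.8
  h <- mr_harmonize(p$exp, p$out)
  expect_equal(h$beta_out[1], -0.1)
  expect_equal(nrow(h), 4)
})

test_that("outcome-significant SNPs are excluded with a reason code", {
  p <- make_pair(5)
  p$out$pval[2] <- 1e-9
  h <- mr_harmonize(p$exp, p$out, outcome_sig_threshold = 5e-8)
  expect_false("rs002" %in% h$snp)
  ex <- exclusions(h)
  expect_equal(ex$reason[ex$snp == "rs002"], "outcome-significant")
})

test_that("palindromic SNPs are dropped unconditionally", {
  p <- make_pair(5)
  p$exp$other_allele[3] <- "T"
  p$out$other_allele[3] <- "T"
  h <- mr_harmonize(p$exp, p$out)
  expect_false("rs003" %in% h$snp)
  expect_equal(exclusions(h)$reason[exclusions(h)$snp == "rs003"],
               "palindromic")
})

test_that("every input SNP lands in the set or the log with one reason", {
  p <- make_pair(8)
  p$exp$other_allele[1] <- "T"            # palindromic
  p$out <- p$out[-2, ]                    # missing in outcome
  p$out$pval[p$out$snp == "rs003"] <- 1e-10  # outcome-significant
  p$out$effect_allele[p$out$snp == "rs004"] <- "C"  # allele mismatch
  h <- mr_harmonize(p$exp, p$out)
  ex <- exclusions(h)
  expect_equal(sort(c(h$snp, ex$snp)), sort(p$exp$snp))
  expect_equal(anyDuplicated(c(h$snp, ex$snp)), 0)
  expect_equal(ex$reason[order(ex$snp)],
               c("palindromic", "missing-in-outcome", "outcome-significant",
                 "allele-mismatch"))
})

test_that("allele-flip involution: pre-flipped input gives an identical set", {
  p <- make_pair(5)
  flipped <- p$out
  flipped$effect_allele <- p$out$other_allele
  flipped$other_allele <- p$out$effect_allele
  flipped$beta <- -p$out$beta
  flipped$eaf <- 1 - p$out$eaf
  h1 <- mr_harmonize(p$exp, p$out)
  h2 <- mr_harmonize(p$exp, flipped)
  expect_equal(as.data.frame(h1), as.data.frame(h2))
})

test_that("harmonization is idempotent", {
  p <- make_pair(6)
  p$out$effect_allele[2] <- "G"
  p$out$other_allele[2] <- "A"
  h1 <- mr_harmonize(p$exp, p$out)
  # rebuild per-trait tables from the harmonized output and rerun
  exp2 <- tibble::tibble(
    snp = h1$snp, chrom = h1$chrom, pos = h1$pos,
    effect_allele = h1$effect_allele, other_allele = h1$other_allele,
    eaf = h1$eaf, beta = h1$beta_exposure, se = h1$se_exposure,
    pval = h1$pval_exposure
  )
  out2 <- dplyr::mutate(exp2, beta = h1$beta_out, se = h1$se_out,
                        pval = h1$pval_out)
  h2 <- mr_harmonize(exp2, out2)
  expect_equal(h2$beta_out, h1$beta_out)
  expect_equal(h2$snp, h1$snp)
  expect_equal(nrow(exclusions(h2)), 0)
})

test_that("simulator output harmonizes against itself with no surprises", {
  study <- simulate_two_sample(sim_config(n_snp = 30, seed = 9,
                                          n_palindromic = 4))
  h <- mr_harmonize(study$exposure, study$outcome,
                    outcome_sig_threshold = 0)
  ex <- exclusions(h)
  expect_setequal(ex$snp, study$truth$palindromic_ids)
  expect_true(all(ex$reason == "palindromic"))
  # no flips: outcome betas carried through unchanged
  kept <- match(h$snp, study$outcome$snp)
  expect_equal(h$beta_out, study$outcome$beta[kept])
})

test_that("swapped simulator labels are flipped back during harmonization", {
  study <- simulate_two_sample(sim_config(n_snp = 40, seed = 12,
                                          swap_fraction = 0.5))
  h <- mr_harmonize(study$exposure, study$outcome,
                    outcome_sig_threshold = 0)
  # after alignment the outcome betas equal the unswapped draws
  swapped <- h$snp %in% study$truth$swapped_ids
  expect_true(any(swapped))
  kept <- match(h$snp, study$outcome$snp)
  expect_equal(h$beta_out[swapped], -study$outcome$beta[kept][swapped])
  expect_equal(h$beta_out[!swapped], study$outcome$beta[kept][!swapped])
})

test_that("proxy SNPs substitute for instruments missing in the outcome", {
  p <- make_pair(5)
  out <- p$out
  out$snp[2] <- "rsproxy"  # rs002 absent; rsproxy present instead
  ld <- ld_table("rs002", "rsproxy", 0.9)
  h <- mr_harmonize(p$exp, out, ld = ld)
  expect_true("rs002" %in% h$snp)
  pr <- attr(h, "proxies")
  expect_equal(pr$proxy[pr$snp == "rs002"], "rsproxy")
  # without the LD table the SNP is simply dropped
  h2 <- mr_harmonize(p$exp[-2, ] |> dplyr::bind_rows(p$exp[2, ]), out)
  expect_false("rs002" %in% h2$snp)
})

test_that("too few surviving SNPs is fatal", {
  p <- make_pair(3)
  p$out$pval[1] <- 1e-12
  expect_error(mr_harmonize(p$exp, p$out), "at least 3")
  # multivariable needs K + 2 survivors
  p4 <- make_pair(4)
  p4$exp$other_allele[4] <- "T"  # palindrome leaves only 3
  expect_error(
    mr_harmonize(list(a = p4$exp, b = p4$exp), p4$out),
    "at least 4"
  )
})
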