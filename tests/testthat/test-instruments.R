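test_that("instrument selection applies a strict p-value threshold", {
  tbl <- tiny_gwas(2)
  tbl$pval <- c(1e-9, 1e-7)
  expect_equal(nrow(select_instruments(tbl, 5e-8)), 1)
  expect_equal(nrow(select_instruments(tbl, 1e-5)), 2)
  expect_error(select_instruments(tbl, 1e-12), "5e-08|1e-12")
})

test_that("selection at large sample size recovers the true instruments", {
  study <- simulate_two_sample(sim_config(
    n_snp = 40, n_exposure_sample = 5e7, gamma_sd = 0.05, seed = 77))
  sel <- select_instruments(study$exposure, 5e-8)
  # every instrument whose true effect clears the detection boundary with
  # margin is recovered; effects drawn near zero may legitimately miss
  strong <- abs(study$truth$gamma) > 8 * study$exposure$se
  expect_true(all(study$truth$snp[strong] %in% sel$snp))
  expect_gte(nrow(sel) / 40, 0.9)
})

test_that("palindromic allele pairs are recognized in both orders", {
  expect_true(is_palindromic("A", "T"))
  expect_true(is_palindromic("T", "A"))
  expect_true(is_palindromic("G", "C"))
  expect_true(is_palindromic("C", "G"))
  expect_false(is_palindromic("A", "G"))
  expect_false(is_palindromic("C", "T"))
})

test_that("clumping keeps distant SNPs and collapses close correlated ones", {
  tbl <- tiny_gwas(2)
  tbl$pos <- c(1e6, 3e6)  # 2 Mb apart
  ld <- ld_table("rs001", "rs002", 0.9)
  out <- clump_instruments(tbl, ld, r2_max = 0.001, window_bp = 1e6)
  expect_equal(nrow(out), 2)

  tbl$pos <- c(1e6, 1.5e6)  # 0.5 Mb apart, r2 = 0.5
  tbl$pval <- c(1e-10, 1e-8)
  ld <- ld_table("rs001", "rs002", 0.5)
  out <- clump_instruments(tbl, ld, r2_max = 0.001, window_bp = 1e6)
  expect_equal(out$snp, "rs001")  # lower p wins
  expect_equal(attr(out, "clumped")$snp, "rs002")
})

test_that("pairs absent from the LD table within the window count as dependent", {
  tbl <- tiny_gwas(2)
  tbl$pos <- c(1e6, 1.5e6)
  out <- clump_instruments(tbl, ld = NULL, r2_max = 0.001, window_bp = 1e6)
  expect_equal(nrow(out), 1)
})

test_that("greedy clumping matches a brute-force oracle on block LD", {
  set.seed(501)
  n <- 50
  tbl <- tibble::tibble(
    snp = sprintf("rs%03d", sample(n)),  # scrambled ids
    chrom = as.character(rep(1:5, each = 10)),
    pos = rep(seq(1e6, by = 4e5, length.out = 10), 5),
    pval = runif(n, 1e-12, 1e-8),
    effect_allele = "A", other_allele = "G",
    eaf = 0.5, beta = 0.1, se = 0.02, n = 1000L
  )
  # block-structured LD: all pairs known, high within 2-SNP blocks
  pairs <- t(combn(n, 2))
  block <- (pairs[, 1] - 1) %/% 2 == (pairs[, 2] - 1) %/% 2
  ld <- ld_table(tbl$snp[pairs[, 1]], tbl$snp[pairs[, 2]],
                 ifelse(block, 0.8, 1e-5))
  r2_mat <- matrix(NA_real_, n, n, dimnames = list(tbl$snp, tbl$snp))
  r2_mat[cbind(pairs[, 1], pairs[, 2])] <- ld$r2
  r2_mat[cbind(pairs[, 2], pairs[, 1])] <- ld$r2

  out <- clump_instruments(tbl, ld, r2_max = 0.001, window_bp = 1e6)
  expect_equal(sort(out$snp), clump_oracle(tbl, r2_mat, 0.001, 1e6))

  # invariance to input row order
  shuf <- tbl[sample(n), ]
  out2 <- clump_instruments(shuf, ld, r2_max = 0.001, window_bp = 1e6)
  expect_setequal(out2$snp, out$snp)
})

test_that("proxy lookup returns the best partner above the threshold", {
  ld <- ld_table(c("rsq", "rsq", "rsq"), c("rsA", "rsB", "rsC"),
                 c(0.95, 0.85, 0.92))
  expect_equal(find_proxy("rsq", c("rsA"), ld), "rsA")
  expect_equal(find_proxy("rsq", c("rsB", "rsC"), ld), "rsC")
  ld2 <- ld_table(c("rsq", "rsq"), c("rsA", "rsB"), c(0.7, 0.75))
  expect_true(is.na(find_proxy("rsq", c("rsA", "rsB"), ld2)))
  # tie on r2 -> lexicographically smallest rsID
  ld3 <- ld_table(c("rsq", "rsq"), c("rsZ", "rsB"), c(0.9, 0.9))
  expect_equal(find_proxy("rsq", c("rsZ", "rsB"), ld3), "rsB")
})

test_that("F statistic and variance explained follow their closed forms", {
  expect_equal(f_statistic(0.1, 0.02), 25)
  expect_equal(f_statistic(0, 0.5), 0)
  expect_equal(f_statistic(-0.37, 0.0037), 1e4)
  expect_equal(variance_explained(0.5, 0.2), 0.02)
  expect_equal(variance_explained(0, 0.4), 0)
  expect_equal(variance_explained(1, 0.4), 0)
  # invariants: sign of beta and eaf relabeling
  expect_equal(variance_explained(0.3, -0.2), variance_explained(0.7, 0.2))
})

test_that("eaf inverted from a known variance share is self-consistent", {
  # a single strong variant with beta -0.37 explaining 4.7% of variance:
  # solve 2p(1-p) beta^2 = 0.047 for the minor-allele root
  beta <- -0.37
  pq <- 0.047 / (2 * beta^2)
  eaf <- (1 - sqrt(1 - 4 * pq)) / 2
  expect_equal(variance_explained(eaf, beta), 0.047, tolerance = 1e-12)
  expect_equal(eaf, 0.2201, tolerance = 1e-3)
})

test_that("strength summary aggregates F and R2 and warns when weak", {
  one <- tibble::tibble(snp = "rs1", beta = 0.1, se = 0.02, eaf = 0.5)
  s <- strength_summary(one)
  expect_equal(s$mean_f, 25)
  expect_equal(s$total_r2, 0.005)
  two <- dplyr::bind_rows(one, dplyr::mutate(one, snp = "rs2"))
  s2 <- strength_summary(two)
  expect_equal(s2$mean_f, 25)
  expect_equal(s2$total_r2, 0.01)

  weak <- tibble::tibble(snp = "rs1", beta = 0.01, se = 0.02, eaf = 0.5)
  expect_warning(strength_summary(weak), "weak-instrument")

  na_eaf <- dplyr::mutate(two, eaf = c(0.5, NA))
  expect_warning(s3 <- strength_summary(na_eaf), "lack eaf")
  expect_equal(s3$total_r2, 0.005)
  expect_equal(s3$n_missing_eaf, 1)
})

test_that("simulated total R2 matches the configured heritability", {
  r2 <- replicate(30, {
    seed <- sample.int(1e6, 1)
    cfg <- sim_config(n_snp = 100, target_r2 = 0.05, seed = seed)
    study <- simulate_two_sample(cfg)
    suppressWarnings(strength_summary(study$exposure))$total_r2
  })
  expect_equal(mean(r2), 0.05, tolerance = 0.2)
})
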