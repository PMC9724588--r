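# Small constructed fixtures shared across test files.

`%||%` <- function(a, b) if (is.null(a)) b else a

# A minimal well-formed GWAS tibble in canonical columns.
tiny_gwas <- function(n = 3, beta = 0.1, se = 0.02, pval = 1e-9,
                      eaf = 0.3, chrom = "1", pos_start = 1e6,
                      ea = "A", oa = "G") {
  tibble::tibble(
    snp = sprintf("rs%03d", seq_len(n)),
    chrom = rep(chrom, n),
    pos = pos_start + 3e6 * (seq_len(n) - 1),
    effect_allele = rep(ea, n),
    other_allele = rep(oa, n),
    eaf = rep(eaf, n),
    beta = rep(beta, n),
    se = rep(se, n),
    pval = rep(pval, n),
    n = rep(100000L, n)
  )
}

# Harmonized input straight from a simulated study (tables already share
# allele orientation when swap_fraction = 0).
sim_input <- function(study, exposure = "exposure", outcome = "outcome") {
  mr_input(study$exposure$beta, study$exposure$se,
           study$outcome$beta, study$outcome$se,
           snp = study$exposure$snp, exposure = exposure, outcome = outcome)
}

# Independent greedy clumping oracle: dense r2 matrix, plain double loop.
clump_oracle <- function(tbl, r2_mat, r2_max, window_bp) {
  ord <- order(tbl$pval, tbl$snp)
  kept <- character()
  for (i in ord) {
    ok <- TRUE
    for (k in kept) {
      j <- match(k, tbl$snp)
      if (tbl$chrom[i] == tbl$chrom[j] &&
          abs(tbl$pos[i] - tbl$pos[j]) <= window_bp) {
        r2 <- r2_mat[tbl$snp[i], tbl$snp[j]]
        if (is.na(r2) || r2 >= r2_max) ok <- FALSE
      }
      if (!ok) break
    }
    if (ok) kept <- c(kept, tbl$snp[i])
  }
  sort(kept)
}
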