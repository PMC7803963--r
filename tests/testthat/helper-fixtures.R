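# Small in-code fixtures shared across the suite.

# Genotype matrix from a raw dosage matrix with evenly spaced positions on
# one chromosome (5 kb apart unless bp is given).
make_geno <- function(dosages, chr = NULL, bp = NULL, a1 = "A", a2 = "G",
                      cohort = NULL) {
  dosages <- as.matrix(dosages)
  p <- ncol(dosages)
  meta <- data.frame(
    snp = sprintf("snp%03d", seq_len(p)),
    chr = if (is.null(chr)) rep(1L, p) else chr,
    bp = if (is.null(bp)) seq_len(p) * 5000L else bp,
    a1 = rep_len(a1, p), a2 = rep_len(a2, p),
    stringsAsFactors = FALSE)
  colnames(dosages) <- meta$snp
  genotype_matrix(dosages, meta, cohort = cohort)
}

# Random genotypes with independent SNPs (for oracle comparisons).
random_geno <- function(n, p, maf = 0.3, seed = 1, cohort = NULL) {
  set.seed(seed)
  make_geno(matrix(rbinom(n * p, 2, maf), n, p), cohort = cohort)
}

make_metab <- function(values, xenobiotic = NULL, cohort = NULL,
                       log_scale = FALSE) {
  values <- as.matrix(values)
  if (is.null(xenobiotic)) xenobiotic <- rep(FALSE, ncol(values))
  if (is.null(cohort)) cohort <- rep("A", nrow(values))
  metabolite_matrix(values, xenobiotic, cohort, log_scale = log_scale)
}

# Brute-force OLS oracle via explicit normal equations; returns beta and se
# for the dosage column when regressed with intercept + covariates.
ols_oracle <- function(y, x, C = NULL) {
  X <- cbind(1, x, C)
  XtX <- t(X) %*% X
  b <- solve(XtX, t(X) %*% y)
  res <- y - X %*% b
  df <- length(y) - ncol(X)
  sigma2 <- sum(res^2) / df
  covb <- sigma2 * solve(XtX)
  list(beta = b[2, 1], se = sqrt(covb[2, 2]), df = df)
}

# A small trained model built directly from weights (no CV), for the
# association-stage tests.
make_model <- function(snps, weights, a1 = "A", a2 = "G",
                       metabolite_id = "met", cv_mean_r = 0.5) {
  m <- fit_polygenic_score(
    data.frame(snp = snps, chr = 1L, bp = seq_along(snps) * 5000L,
               p = rep(1e-6, length(snps)), beta = weights,
               se = rep(0.1, length(snps)), stringsAsFactors = FALSE),
    make_geno(matrix(1, 2, length(snps)), a1 = a1, a2 = a2),
    p_threshold = 1e-2, metabolite_id = metabolite_id)
  m$cv_mean_r <- cv_mean_r
  m$cv_r2 <- cv_mean_r^2
  m
}

# Independent brute-force clumping oracle: literal greedy procedure with
# naive loops, used to cross-check the implementation.
clump_oracle <- function(gwas, panel, r2_max, window_kb, p_max) {
  cand <- gwas[!is.na(gwas$p) & gwas$p < p_max, , drop = FALSE]
  cand <- cand[cand$snp %in% panel$snp_meta$snp, , drop = FALSE]
  picked <- character(0)
  alive <- cand[order(cand$p, cand$snp), , drop = FALSE]
  while (nrow(alive) > 0) {
    top <- alive[1, ]
    picked <- c(picked, top$snp)
    keep <- logical(nrow(alive))
    for (i in seq_len(nrow(alive))) {
      if (alive$snp[i] == top$snp) next
      if (alive$chr[i] == top$chr &&
          abs(alive$bp[i] - top$bp) <= window_kb * 1000) {
        r <- suppressWarnings(cor(panel$dosages[, top$snp],
                                  panel$dosages[, alive$snp[i]]))
        if (is.na(r)) r <- 0
        if (r^2 >= r2_max) next
      }
      keep[i] <- TRUE
    }
    alive <- alive[keep, , drop = FALSE]
  }
  picked
}
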