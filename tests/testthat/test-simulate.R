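test_that("invalid configurations are rejected", {
  expect_error(sim_config(n_snps = 0), "positive")
  expect_error(sim_config(n_samples_per_cohort = c(0, 10)), "positive")
  expect_error(sim_config(n_snps = 105, ld_block_size = 10), "partition")
  expect_error(sim_config(maf_range = c(0.01, 0.5)), "maf_range")
  expect_error(sim_config(h2 = 1), "h2")
  expect_error(sim_config(ld_rho = 1), "ld_rho")
})

test_that("identical seeds give bit-identical genotypes and metabolomes", {
  cfg <- sim_config(n_samples_per_cohort = c(40, 30), n_snps = 50,
                    n_metabolites = 5, seed = 99)
  g1 <- simulate_genotypes(cfg)
  g2 <- simulate_genotypes(cfg)
  expect_identical(g1, g2)
  s1 <- simulate_metabolome(g1, cfg)
  s2 <- simulate_metabolome(g2, cfg)
  expect_identical(s1$metabolites, s2$metabolites)
  expect_identical(s1$truth, s2$truth)
})

test_that("dosages are hard calls with MAF in range and ordered positions", {
  cfg <- sim_config(n_samples_per_cohort = c(400, 400), n_snps = 200,
                    ld_block_size = 10, maf_range = c(0.1, 0.4), seed = 3)
  g <- simulate_genotypes(cfg)
  expect_true(all(g$dosages %in% 0:2))
  f <- colMeans(g$dosages) / 2
  expect_true(all(f > 0.1 - 0.07 & f < 0.4 + 0.07)) # range +/- sampling error
  for (ch in unique(g$snp_meta$chr)) {
    bp <- g$snp_meta$bp[g$snp_meta$chr == ch]
    expect_true(all(diff(bp) > 0))
  }
  # one block spans well under the 1000 kb clumping window
  b1 <- g$snp_meta$bp[1:10]
  expect_lt(max(b1) - min(b1), 1e6)
})

test_that("ld_rho = 0 gives independent SNPs", {
  cfg <- sim_config(n_samples_per_cohort = c(500, 500), n_snps = 50,
                    ld_block_size = 5, ld_rho = 0, seed = 5)
  g <- simulate_genotypes(cfg)
  cc <- cor(g$dosages)
  off <- abs(cc[upper.tri(cc)])
  expect_lt(mean(off), 3 / sqrt(nrow(g$dosages)))
})

test_that("adjacent within-block dosage r2 matches ld_rho^2 and decays", {
  cfg <- sim_config(n_samples_per_cohort = c(1000, 1000), n_snps = 100,
                    ld_block_size = 10, ld_rho = 0.9, seed = 7)
  g <- simulate_genotypes(cfg)
  starts <- seq(1, 91, 10)
  adj_r2 <- sapply(starts, function(s) cor(g$dosages[, s], g$dosages[, s + 1])^2)
  expect_lt(abs(mean(adj_r2) - 0.81), 0.05)
  # distance-2 r2 should be near rho^4
  r2_2 <- sapply(starts, function(s) cor(g$dosages[, s], g$dosages[, s + 2])^2)
  expect_lt(abs(mean(r2_2) - 0.9^4), 0.07)
  # across blocks: uncorrelated
  across <- sapply(starts[-10], function(s) cor(g$dosages[, s], g$dosages[, s + 10]))
  expect_lt(mean(abs(across)), 3 / sqrt(nrow(g$dosages)))
})

test_that("planted single-mQTL effect is recovered by OLS within 2 SE", {
  cfg <- sim_config(n_samples_per_cohort = c(1000, 1000), n_snps = 50,
                    ld_block_size = 5, n_metabolites = 4, h2 = 0.3,
                    n_causal_snps = 1,
                    missingness_rates = list(nonxeno = 0, xeno = 0),
                    xenobiotic_fraction = 0, seed = 11)
  g <- simulate_genotypes(cfg)
  sim <- simulate_metabolome(g, cfg)
  for (met in colnames(sim$metabolites$values)) {
    truth <- sim$truth$causal_snps_per_metabolite[[met]]
    y <- log10(sim$metabolites$values[, met])
    o <- ols_oracle(y, g$dosages[, truth$snp])
    expect_lt(abs(o$beta - truth$beta), 2 * o$se)
  }
  # realized h2 of the log10 values is near the target
  met <- colnames(sim$metabolites$values)[1]
  truth <- sim$truth$causal_snps_per_metabolite[[met]]
  y <- log10(sim$metabolites$values[, met])
  gsc <- g$dosages[, truth$snp] * truth$beta
  h2_real <- var(gsc) / var(y)
  expect_lt(abs(h2_real - 0.3), 0.1)
})

test_that("xenobiotic_fraction = 0 flags nothing; missingness follows class", {
  cfg <- sim_config(n_samples_per_cohort = c(100, 100), n_snps = 20,
                    ld_block_size = 5, n_metabolites = 10,
                    xenobiotic_fraction = 0, seed = 13)
  sim <- simulate_metabolome(simulate_genotypes(cfg), cfg)
  expect_false(any(sim$metabolites$xenobiotic))
  # non-xenobiotic missingness is left-censoring: all missing cells sit below
  # the observed minimum of their metabolite
  v <- sim$metabolites$values
  for (j in seq_len(ncol(v))) {
    expect_equal(mean(is.na(v[, j])), 0.05, tolerance = 0.015)
  }
})

test_that("null phenotype sumstats have uniform p-values", {
  cfg <- sim_config(n_samples_per_cohort = c(50, 50), n_snps = 2000,
                    ld_block_size = 5, ld_rho = 0, n_metabolites = 2,
                    seed = 17)
  sim <- simulate_metabolome(simulate_genotypes(cfg), cfg)
  tr <- plant_phenotype_effect(sim$truth, "met001", 0, n = 2000)
  ss <- simulate_phenotype_sumstats(tr, cfg)
  expect_equal(nrow(ss), 2000)
  expect_lt(abs(mean(ss$p < 0.05) - 0.05), 0.02)
})

test_that("a strongly causal SNP tops the phenotype GWAS and flips with the effect", {
  cfg <- sim_config(n_samples_per_cohort = c(50, 50), n_snps = 60,
                    ld_block_size = 10, ld_rho = 0, n_metabolites = 2,
                    h2 = 0.4, n_causal_snps = 1, seed = 19)
  sim <- simulate_metabolome(simulate_genotypes(cfg), cfg)
  causal <- sim$truth$causal_snps_per_metabolite[["met001"]]
  tr_pos <- plant_phenotype_effect(sim$truth, "met001", 2.0, n = 5000)
  ss_pos <- simulate_phenotype_sumstats(tr_pos, cfg, sample_seed = 101)
  expect_equal(ss_pos$snp[which.min(ss_pos$p)], causal$snp)
  tr_neg <- plant_phenotype_effect(sim$truth, "met001", -2.0, n = 5000)
  ss_neg <- simulate_phenotype_sumstats(tr_neg, cfg, sample_seed = 101)
  i <- match(causal$snp, ss_pos$snp)
  expect_true(sign(ss_neg$z[i]) == -sign(ss_pos$z[i]))
  expect_error(plant_phenotype_effect(sim$truth, "met001", 1, n = 10),
               ">= 50")
  expect_error(simulate_phenotype_sumstats(sim$truth, cfg), "planted")
})
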