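stats_row <- function(snp, a1, a2, beta = NA, se = NA, or = NA, z = NA,
                      freq = NA, n = NA, chr = 1L, bp = NULL) {
  data.frame(snp = snp, chr = chr,
             bp = if (is.null(bp)) seq_along(snp) * 5000L else bp,
             effect_allele = a1, other_allele = a2,
             beta = beta, se = se, or = or, z = z, freq = freq, n = n,
             stringsAsFactors = FALSE)
}

test_that("harmonization orients alleles and converts effect scales", {
  m <- make_model(c("snp001", "snp002", "snp003", "snp004"),
                  c(0.5, -0.2, 0.1, 0.3),
                  a1 = c("A", "A", "A", "A"), a2 = c("G", "G", "G", "T"))
  st <- rbind(
    stats_row("snp001", "A", "G", beta = 0, se = 0.1, or = 1.0), # identical
    stats_row("snp002", "G", "A", z = 2.5, beta = 0.25, se = 0.1), # swapped
    stats_row("snp003", "T", "C", beta = 0.4, se = 0.1))          # complement
  h <- harmonize_sumstats(m, st)
  expect_equal(h$flag, c("as_is", "sign_flipped", "strand_complemented",
                         "dropped_ambiguous"))
  expect_equal(h$beta[1], 0)          # ln(OR = 1) = 0
  expect_equal(h$z[2], -2.5)          # swap flips the sign
  expect_equal(h$beta[3], 0.4)        # complement, same orientation
  expect_true(is.na(h$z[4]))          # A/T ambiguous dropped
})

test_that("z-only records reconstruct a self-consistent beta/se", {
  m <- make_model("snp001", 1)
  st <- stats_row("snp001", "A", "G", z = 3.2, freq = 0.25, n = 50000)
  h <- harmonize_sumstats(m, st)
  expect_equal(h$beta / h$se, 3.2, tolerance = 1e-6)
  expect_equal(h$z, 3.2)
  # no overlap at all is an error
  st2 <- stats_row("other", "A", "G", beta = 1, se = 1)
  expect_error(harmonize_sumstats(m, st2), "untestable")
})

test_that("z-score imputation handles identity, perfect proxy and no-LD", {
  set.seed(81)
  base <- rbinom(200, 2, 0.4)
  other <- rbinom(200, 2, 0.4)
  panel <- make_geno(cbind(base, base, other)) # snp002 in perfect LD w/ snp001
  m <- make_model(c("snp001", "snp002", "snp003"), c(1, 1, 1))
  st <- stats_row("snp001", "A", "G", beta = 0.3, se = 0.1)
  st$z <- 3
  h <- harmonize_sumstats(m, st)
  expect_equal(h$flag, c("as_is", "missing", "missing"))
  h0 <- impute_missing_zscores(h, panel, ridge_eps = 0)
  expect_equal(h0$z[1], 3)               # observed stays untouched
  expect_equal(h0$z[2], 3, tolerance = 1e-9)  # r = 1 proxy
  expect_equal(h0$impute_r2[2], 1, tolerance = 1e-9)
  expect_lt(abs(h0$z[3]), 0.5)           # near-zero correlation -> shrunk
  # exactly uncorrelated -> exactly the prior mean 0
  panel2 <- make_geno(cbind(rep(c(0, 2), 50), rep(c(0, 0, 2, 2), 25)))
  m2 <- make_model(c("snp001", "snp002"), c(1, 1))
  st2 <- stats_row("snp001", "A", "G", beta = 0.3, se = 0.1)
  h2 <- impute_missing_zscores(harmonize_sumstats(m2, st2), panel2,
                               ridge_eps = 0.1)
  expect_equal(h2$z[2], 0)
  expect_equal(h2$impute_r2[2], 0)
})

test_that("the weighted-score statistic reduces and scales correctly", {
  # single SNP with unit weight: Z equals the SNP's own z
  set.seed(82)
  panel1 <- make_geno(cbind(rbinom(300, 2, 0.3)))
  m1 <- make_model("snp001", 0.37)
  st <- stats_row("snp001", "A", "G", beta = 0.2, se = 0.1)
  h <- harmonize_sumstats(m1, st)
  a <- badgers_association(m1, h, panel1)
  expect_equal(a$z_score, 2.0, tolerance = 1e-12)
  expect_equal(a$p, 2 * pnorm(-2), tolerance = 1e-12)

  # two exactly uncorrelated SNPs, equal sd and weight, z = (2, 2)
  panel2 <- make_geno(cbind(rep(c(0, 2), 50), rep(c(0, 0, 2, 2), 25)))
  m2 <- make_model(c("snp001", "snp002"), c(1, 1))
  st2 <- stats_row(c("snp001", "snp002"), "A", "G", beta = c(0.2, 0.2),
                   se = c(0.1, 0.1))
  st2$z <- c(2, 2)
  h2 <- harmonize_sumstats(m2, st2)
  a2 <- badgers_association(m2, h2, panel2)
  expect_equal(a2$z_score, 4 / sqrt(2), tolerance = 1e-12)

  # scaling all weights leaves Z unchanged
  m3 <- make_model(c("snp001", "snp002"), c(17, 17))
  a3 <- badgers_association(m3, h2, panel2)
  expect_equal(a3$z_score, a2$z_score, tolerance = 1e-12)
})

test_that("complement-and-flip of the phenotype file changes nothing", {
  set.seed(83)
  panel <- random_geno(300, 5, seed = 83)
  m <- make_model(paste0("snp00", 1:5), c(0.5, -0.3, 0.2, 0.1, -0.4))
  st <- stats_row(paste0("snp00", 1:5), "A", "G",
                  beta = c(0.1, -0.2, 0.3, 0, 0.2),
                  se = rep(0.1, 5))
  st$z <- st$beta / st$se
  a1 <- badgers_association(m, harmonize_sumstats(m, st), panel)
  st_flip <- st
  st_flip$effect_allele <- "C" # complement of G
  st_flip$other_allele <- "T"  # complement of A -> swapped + complemented
  st_flip$beta <- -st$beta
  st_flip$z <- -st$z
  a2 <- badgers_association(m, harmonize_sumstats(m, st_flip), panel)
  expect_identical(a1$z_score, a2$z_score)
  expect_identical(a1$p, a2$p)
})

test_that("q-values follow the step-up procedure and the Storey estimate", {
  # hand-executed BH on {0.01, 0.02, 0.03, 0.04}
  q <- compute_qvalues(c(0.01, 0.02, 0.03, 0.04), method = "bh")
  expect_equal(q$q, rep(0.04, 4))
  expect_equal(q$pi0, 1)
  # all p = 1 -> all q = 1
  q1 <- compute_qvalues(rep(1, 5), method = "storey")
  expect_equal(q1$q, rep(1, 5))
  # q-values are monotone in p
  set.seed(84)
  p <- runif(200)^1.5
  qs <- compute_qvalues(p, method = "storey")
  expect_true(all(diff(qs$q[order(p)]) >= -1e-12))
  expect_true(all(qs$q >= qs$pi0 * p.adjust(p, "BH") - 1e-12))
  expect_error(compute_qvalues(c(0.5, 0)), "0, 1")
  expect_length(compute_qvalues(numeric(0))$q, 0)
})
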