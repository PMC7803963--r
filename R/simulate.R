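#' Configuration for the synthetic cohort generator
#'
#' Defines the study conditions emulated by the generator: two cohorts of
#' unrelated samples, LD-blocked common variants, metabolites with a sparse or
#' polygenic genetic architecture on the log10 scale, age/sex/batch
#' covariates, and class-specific missingness (below-detection censoring for
#' endogenous compounds, genuine absence for xenobiotics).
#'
#' @param n_samples_per_cohort integer vector of length 2 (or a scalar used
#'   for both cohorts). Defaults to 155 and 136, typical analyzed sizes for a
#'   two-cohort CSF metabolomics study.
#' @param n_snps total number of SNPs; must be an exact multiple of
#'   `ld_block_size` (blocks partition the SNPs).
#' @param n_metabolites number of metabolites.
#' @param maf_range allele-frequency range for block frequencies; the lower
#'   bound must be at least 0.05, matching the analysis MAF floor.
#' @param ld_block_size number of SNPs per LD block.
#' @param ld_rho target correlation between adjacent SNP dosages within a
#'   block; correlation decays as `ld_rho^distance` and is ~0 across blocks.
#' @param h2 narrow-sense heritability of each metabolite's log10 abundance.
#' @param n_causal_snps causal SNPs per metabolite (1 = sparse mQTL
#'   architecture; larger values give polygenic metabolites).
#' @param xenobiotic_fraction fraction of metabolites flagged xenobiotic.
#' @param missingness_rates list with elements `nonxeno` (fraction of each
#'   endogenous metabolite left-censored below its detection quantile) and
#'   `xeno` (per-cell probability that a xenobiotic is absent from a sample).
#' @param seed integer seed; identical seeds give bit-identical output.
#'
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_samples_per_cohort = c(155L, 136L),
                       n_snps = 600L,
                       n_metabolites = 30L,
                       maf_range = c(0.05, 0.5),
                       ld_block_size = 10L,
                       ld_rho = 0.8,
                       h2 = 0.3,
                       n_causal_snps = 1L,
                       xenobiotic_fraction = 0.15,
                       missingness_rates = list(nonxeno = 0.05, xeno = 0.30),
                       seed = 1L) {
  if (length(n_samples_per_cohort) == 1L) {
    n_samples_per_cohort <- rep(n_samples_per_cohort, 2L)
  }
  if (any(n_samples_per_cohort <= 0) || n_snps <= 0 || n_metabolites <= 0 ||
      ld_block_size <= 0) {
    stop("sim_config: dimensions must be positive")
  }
  if (n_snps %% ld_block_size != 0L) {
    stop("sim_config: n_snps must be a multiple of ld_block_size ",
         "(blocks partition SNPs exactly)")
  }
  if (maf_range[1] < 0.05 || maf_range[2] > 0.5 || maf_range[1] > maf_range[2]) {
    stop("sim_config: maf_range must lie within [0.05, 0.5]")
  }
  if (ld_rho < 0 || ld_rho >= 1) stop("sim_config: ld_rho must be in [0, 1)")
  if (h2 < 0 || h2 >= 1) stop("sim_config: h2 must be in [0, 1)")
  if (n_causal_snps < 0 || n_causal_snps > n_snps) {
    stop("sim_config: n_causal_snps out of range")
  }
  if (xenobiotic_fraction < 0 || xenobiotic_fraction > 1) {
    stop("sim_config: xenobiotic_fraction must be a proportion")
  }
  structure(list(n_samples_per_cohort = as.integer(n_samples_per_cohort),
                 n_snps = as.integer(n_snps),
                 n_metabolites = as.integer(n_metabolites),
                 maf_range = maf_range,
                 ld_block_size = as.integer(ld_block_size),
                 ld_rho = ld_rho,
                 h2 = h2,
                 n_causal_snps = as.integer(n_causal_snps),
                 xenobiotic_fraction = xenobiotic_fraction,
                 missingness_rates = missingness_rates,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# SNP metadata (block frequencies, positions, alleles) is a pure function of
# the seed, so fresh samples for a phenotype GWAS share the same variants.
.sim_snp_meta <- function(config) {
  set.seed(config$seed)
  n_blocks <- config$n_snps %/% config$ld_block_size
  block_freq <- stats::runif(n_blocks, config$maf_range[1], config$maf_range[2])
  blocks_per_chr <- 20L
  block_chr <- (seq_len(n_blocks) - 1L) %/% blocks_per_chr + 1L
  block_pos_in_chr <- (seq_len(n_blocks) - 1L) %% blocks_per_chr
  # blocks 2 Mb apart (beyond the 1000 kb clumping window), SNPs 5 kb apart
  # (a block spans well under 1000 kb)
  bp <- rep(block_pos_in_chr * 2e6 + 1, each = config$ld_block_size) +
    (seq_len(config$ld_block_size) - 1L) * 5000
  meta <- data.frame(
    snp = sprintf("rs%05d", seq_len(config$n_snps)),
    chr = rep(block_chr, each = config$ld_block_size),
    bp = as.integer(bp),
    a1 = "A", a2 = "G",
    maf = rep(block_freq, each = config$ld_block_size),
    block = rep(seq_len(n_blocks), each = config$ld_block_size),
    stringsAsFactors = FALSE)
  meta
}

# One haplotype block: allele j copies allele j-1 with probability rho,
# otherwise is a fresh Bernoulli(f) draw. Marginals stay Bernoulli(f) and
# corr(allele_j, allele_{j+d}) = rho^d exactly, so summing two independent
# haplotypes gives dosages with the same geometric LD decay.
.sim_hap_block <- function(n, size, f, rho) {
  h <- matrix(0L, n, size)
  h[, 1] <- stats::rbinom(n, 1L, f)
  if (size > 1L) {
    for (j in 2:size) {
      copy <- stats::runif(n) < rho
      fresh <- stats::rbinom(n, 1L, f)
      h[, j] <- ifelse(copy, h[, j - 1L], fresh)
    }
  }
  h
}

.sim_dosages <- function(meta, n, config, sample_seed) {
  set.seed(sample_seed %% .Machine$integer.max)
  d <- matrix(0L, n, nrow(meta))
  for (b in unique(meta$block)) {
    idx <- which(meta$block == b)
    f <- meta$maf[idx[1]]
    d[, idx] <- .sim_hap_block(n, length(idx), f, config$ld_rho) +
      .sim_hap_block(n, length(idx), f, config$ld_rho)
  }
  d
}

#' Simulate LD-blocked genotypes for two cohorts
#'
#' Dosages are hard calls in `{0, 1, 2}` built from two independent
#' haplotypes per sample. Within a block adjacent dosages have correlation
#' `ld_rho` (decaying geometrically with distance); across blocks SNPs are
#' independent. Allele frequencies are constant within a block and drawn from
#' `maf_range`, so realized MAFs respect the analysis MAF floor up to
#' sampling error.
#'
#' @param config a [sim_config()].
#' @param n_samples optional total sample count overriding the two-cohort
#'   default (used to draw fresh samples for phenotype GWAS simulation; such
#'   samples carry a single cohort label `"SIM"`).
#' @param sample_seed seed for the sample draw; SNP metadata always derives
#'   from `config$seed`, so different `sample_seed`s give fresh individuals at
#'   the same variants.
#' @return A [genotype_matrix()] with cohort labels.
#' @export
simulate_genotypes <- function(config, n_samples = NULL,
                               sample_seed = config$seed + 1L) {
  stopifnot(inherits(config, "sim_config"))
  meta <- .sim_snp_meta(config)
  if (is.null(n_samples)) {
    n <- sum(config$n_samples_per_cohort)
    cohort <- rep(c("COHORT1", "COHORT2"), config$n_samples_per_cohort)
  } else {
    if (n_samples <= 0) stop("n_samples must be positive")
    n <- as.integer(n_samples)
    cohort <- rep("SIM", n)
  }
  d <- .sim_dosages(meta, n, config, sample_seed)
  rownames(d) <- sprintf("%s_%05d", cohort, seq_len(n))
  genotype_matrix(d, meta[, c("snp", "chr", "bp", "a1", "a2", "maf")],
                  cohort = cohort)
}

#' Simulate sample covariates (age, sex, batch)
#'
#' Age at draw is normal around the mid-60s, sex is about two-thirds female,
#' and batch coincides with cohort membership (the batch covariate is what a
#' genotyping-round indicator controls for in the association model).
#'
#' @param genotypes a [genotype_matrix()] carrying cohort labels.
#' @param config a [sim_config()].
#' @return data frame with columns `sample`, `cohort`, `age`, `sex`
#'   (0 = male, 1 = female).
#' @export
simulate_covariates <- function(genotypes, config) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  n <- nrow(genotypes$dosages)
  set.seed(config$seed + 2L)
  data.frame(sample = rownames(genotypes$dosages),
             cohort = genotypes$cohort,
             age = round(pmin(85, pmax(45, stats::rnorm(n, 63, 7))), 1),
             sex = stats::rbinom(n, 1L, 0.65),
             stringsAsFactors = FALSE)
}

#' Simulate a metabolome with planted genetic architecture
#'
#' Each metabolite's log10 abundance is a linear genetic score over
#' `n_causal_snps` randomly placed causal SNPs (scaled so the genetic variance
#' fraction equals `h2`), plus small age/sex/batch effects and Gaussian
#' noise; abundances are `10^log10` values, median-scaled per metabolite, so
#' raw values show the right-skew typical of relative-abundance data while
#' log10 values are Gaussian. Missingness is injected per metabolite class:
#' endogenous metabolites are left-censored below their detection quantile;
#' xenobiotics go missing completely at random (genuine absence).
#'
#' @param genotypes a [genotype_matrix()] from [simulate_genotypes()].
#' @param config a [sim_config()].
#' @param covariates optional covariate table from [simulate_covariates()];
#'   generated if omitted.
#' @return list with elements `metabolites` (a [metabolite_matrix()]),
#'   `covariates`, and `truth` (a `sim_truth` object storing the causal SNPs
#'   and their per-dosage-unit effects on the log10 scale).
#' @export
simulate_metabolome <- function(genotypes, config, covariates = NULL) {
  stopifnot(inherits(genotypes, "genotype_matrix"),
            inherits(config, "sim_config"))
  if (config$h2 >= 1) stop("h2 must be < 1")
  n <- nrow(genotypes$dosages)
  if (n == 0L) stop("genotypes are empty")
  if (is.null(covariates)) covariates <- simulate_covariates(genotypes, config)
  m <- config$n_metabolites
  set.seed(config$seed + 3L)
  n_xeno <- round(config$xenobiotic_fraction * m)
  xeno <- rep(FALSE, m)
  if (n_xeno > 0) xeno[sample.int(m, n_xeno)] <- TRUE

  age_c <- as.numeric(scale(covariates$age))
  sex_c <- covariates$sex - mean(covariates$sex)
  batch_c <- as.numeric(covariates$cohort == covariates$cohort[n]) # 2nd cohort shift
  cov_raw <- 0.5 * age_c + 0.3 * sex_c + 0.6 * (batch_c - mean(batch_c))
  cov_sd <- stats::sd(cov_raw)
  cov_share <- 0.15 # fraction of non-genetic variance carried by covariates

  values <- matrix(NA_real_, n, m,
                   dimnames = list(rownames(genotypes$dosages),
                                   sprintf("met%03d", seq_len(m))))
  causal <- vector("list", m)
  names(causal) <- colnames(values)
  h2 <- config$h2
  for (j in seq_len(m)) {
    if (config$n_causal_snps > 0 && h2 > 0) {
      idx <- sample.int(config$n_snps, config$n_causal_snps)
      b_raw <- stats::rnorm(config$n_causal_snps)
      gs_raw <- genotypes$dosages[, idx, drop = FALSE] %*% b_raw
      s <- stats::sd(gs_raw)
      scale_fac <- if (s > 0) sqrt(h2) / s else 0
      beta <- b_raw * scale_fac
      genetic <- as.numeric(gs_raw) * scale_fac
      causal[[j]] <- data.frame(snp = genotypes$snp_meta$snp[idx],
                                beta = beta, stringsAsFactors = FALSE)
    } else {
      genetic <- numeric(n)
      causal[[j]] <- data.frame(snp = character(0), beta = numeric(0),
                                stringsAsFactors = FALSE)
    }
    cov_part <- if (cov_sd > 0) {
      cov_raw / cov_sd * sqrt(cov_share * (1 - h2))
    } else numeric(n)
    noise <- stats::rnorm(n, 0, sqrt((1 - cov_share) * (1 - h2)))
    logm <- genetic - mean(genetic) + cov_part + noise
    v <- 10^logm
    values[, j] <- v / stats::median(v)
  }

  # missingness injection
  rate_nx <- config$missingness_rates$nonxeno
  rate_x <- config$missingness_rates$xeno
  for (j in seq_len(m)) {
    if (xeno[j]) {
      if (rate_x > 0) values[stats::runif(n) < rate_x, j] <- NA
    } else if (rate_nx > 0) {
      cut <- stats::quantile(values[, j], rate_nx, type = 7)
      values[values[, j] < cut, j] <- NA
    }
  }

  truth <- structure(list(causal_snps_per_metabolite = causal,
                          metabolite_phenotype_effect = NULL,
                          phenotype_gwas_n = NULL),
                     class = "sim_truth")
  list(metabolites = metabolite_matrix(values, xeno, genotypes$cohort),
       covariates = covariates,
       truth = truth)
}

#' Plant a metabolite-to-phenotype effect in the simulation truth
#'
#' @param truth a `sim_truth` from [simulate_metabolome()].
#' @param metabolite metabolite identifier (must exist in the truth).
#' @param effect signed scalar effect of the metabolite's genetic score on the
#'   downstream phenotype (0 plants a null).
#' @param n sample size of the simulated phenotype GWAS (>= 50).
#' @return The updated `sim_truth`.
#' @export
plant_phenotype_effect <- function(truth, metabolite, effect, n = 10000L) {
  stopifnot(inherits(truth, "sim_truth"))
  if (!metabolite %in% names(truth$causal_snps_per_metabolite)) {
    stop("unknown metabolite: ", metabolite)
  }
  if (!is.finite(effect)) stop("effect must be finite")
  if (n < 50) stop("phenotype_gwas_n must be >= 50 (se estimates unstable)")
  truth$metabolite_phenotype_effect <-
    stats::setNames(effect, metabolite)
  truth$phenotype_gwas_n <- as.integer(n)
  truth
}

#' Simulate phenotype GWAS summary statistics under the planted effect
#'
#' Draws a fresh sample of `phenotype_gwas_n` individuals from the same
#' genotype generator, builds the phenotype as
#' `effect x (true genetic score of the metabolite) + N(0, 1)` noise, and
#' emits per-SNP marginal regression summary statistics (beta, se, z, p, n)
#' for every SNP.
#'
#' @param truth a `sim_truth` with a planted effect
#'   (see [plant_phenotype_effect()]).
#' @param config the [sim_config()] the truth was generated under.
#' @param sample_seed seed for the fresh phenotype-cohort draw; vary it to get
#'   replicate summary-statistic sets for the same truth.
#' @return data frame of class `gwas_sumstats` with columns `snp`, `chr`,
#'   `bp`, `effect_allele`, `other_allele`, `freq`, `beta`, `se`, `z`, `p`,
#'   `n`.
#' @export
simulate_phenotype_sumstats <- function(truth, config,
                                        sample_seed = config$seed + 1000L) {
  stopifnot(inherits(truth, "sim_truth"), inherits(config, "sim_config"))
  if (is.null(truth$metabolite_phenotype_effect)) {
    stop("truth has no planted metabolite_phenotype_effect; ",
         "call plant_phenotype_effect() first")
  }
  n <- truth$phenotype_gwas_n
  if (is.null(n) || n < 50) stop("phenotype_gwas_n must be >= 50")
  g <- simulate_genotypes(config, n_samples = n, sample_seed = sample_seed)
  met <- names(truth$metabolite_phenotype_effect)
  eff <- unname(truth$metabolite_phenotype_effect)
  cs <- truth$causal_snps_per_metabolite[[met]]
  gs <- if (nrow(cs) > 0) {
    as.numeric(g$dosages[, cs$snp, drop = FALSE] %*% cs$beta)
  } else numeric(n)
  set.seed((sample_seed + 7L) %% .Machine$integer.max)
  y <- eff * gs + stats::rnorm(n)

  d <- g$dosages
  dc <- sweep(d, 2, colMeans(d))
  yc <- y - mean(y)
  ss_g <- colSums(dc^2)
  ok <- ss_g > 0
  beta <- se <- rep(NA_real_, ncol(d))
  beta[ok] <- colSums(dc[, ok, drop = FALSE] * yc) / ss_g[ok]
  rss <- sum(yc^2) - beta[ok]^2 * ss_g[ok]
  sigma2 <- rss / (n - 2)
  se[ok] <- sqrt(sigma2 / ss_g[ok])
  z <- beta / se
  p <- 2 * stats::pnorm(-abs(z))
  out <- data.frame(snp = g$snp_meta$snp, chr = g$snp_meta$chr,
                    bp = g$snp_meta$bp,
                    effect_allele = g$snp_meta$a1,
                    other_allele = g$snp_meta$a2,
                    freq = colMeans(d) / 2,
                    beta = beta, se = se, z = z, p = p, n = n,
                    stringsAsFactors = FALSE)
  class(out) <- c("gwas_sumstats", "data.frame")
  out
}
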