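#' Greedy LD clumping of GWAS results
#'
#' Restricts to SNPs with `p < p_max`, then repeatedly takes the remaining
#' SNP with the smallest p-value as an index SNP and removes every remaining
#' SNP on the same chromosome within `window_kb` whose squared dosage
#' correlation with the index (estimated in `ld_panel`) is at least
#' `r2_max`. Surviving index SNPs are therefore approximately independent:
#' pairwise r-squared within a window is below `r2_max`.
#'
#' @param gwas a `gwas_result` data frame.
#' @param ld_panel a [genotype_matrix()] used for LD estimation; GWAS SNPs
#'   absent from the panel are dropped with a warning.
#' @param r2_max squared-correlation threshold (default 0.1).
#' @param window_kb window half-width in kilobases (default 1000).
#' @param p_max p-value inclusion threshold (default 0.01, strict `<`).
#' @return data frame of index SNPs ordered by selection (ascending p):
#'   `snp`, `chr`, `bp`, `p`, `beta`, `se`.
#' @export
ld_clump <- function(gwas, ld_panel, r2_max = 0.1, window_kb = 1000,
                     p_max = 0.01) {
  stopifnot(inherits(ld_panel, "genotype_matrix"))
  if (r2_max <= 0 || r2_max >= 1) stop("r2_max must be in (0, 1)")
  if (window_kb <= 0) stop("window_kb must be positive")
  cand <- gwas[!is.na(gwas$p) & gwas$p < p_max, , drop = FALSE]
  in_panel <- cand$snp %in% ld_panel$snp_meta$snp
  if (any(!in_panel)) {
    warning(sum(!in_panel), " GWAS SNPs absent from the LD panel; dropped")
    cand <- cand[in_panel, , drop = FALSE]
  }
  empty <- cand[0, c("snp", "chr", "bp", "p", "beta", "se"), drop = FALSE]
  if (nrow(cand) == 0L) return(empty)
  cand <- cand[order(cand$p, cand$snp), , drop = FALSE]
  dos <- ld_panel$dosages[, cand$snp, drop = FALSE]
  window_bp <- window_kb * 1000
  alive <- rep(TRUE, nrow(cand))
  picked <- integer(0)
  while (any(alive)) {
    i <- which(alive)[1] # smallest remaining p (cand is p-ordered)
    picked <- c(picked, i)
    alive[i] <- FALSE
    near <- which(alive & cand$chr == cand$chr[i] &
                    abs(cand$bp - cand$bp[i]) <= window_bp)
    if (length(near) > 0) {
      r <- suppressWarnings(
        stats::cor(dos[, i], dos[, near, drop = FALSE]))
      r[is.na(r)] <- 0
      alive[near[r^2 >= r2_max]] <- FALSE
    }
  }
  cand[picked, c("snp", "chr", "bp", "p", "beta", "se"), drop = FALSE]
}

.model_family <- function(alpha) {
  if (alpha == 1) "lasso" else if (alpha == 0) "ridge" else "elastic_net"
}

.new_model <- function(metabolite_id, family, alpha = NA_real_,
                       lambda = NA_real_, p_threshold = NA_real_,
                       weights, covariate_coefficients = NULL) {
  structure(list(metabolite_id = metabolite_id, family = family,
                 alpha = alpha, lambda = lambda, p_threshold = p_threshold,
                 weights = weights,
                 covariate_coefficients = covariate_coefficients,
                 cv_mean_r = NA_real_, cv_r2 = NA_real_,
                 n_snps_mean = NA_real_),
            class = "metabolite_model")
}

#' Fit one penalized genetic prediction model
#'
#' Minimizes `(1/2n) * RSS + lambda * (alpha*||b||_1 + (1-alpha)/2*||b||_2^2)`
#' over SNP weights `b`, with covariates and the intercept left unpenalized.
#' SNP columns are standardized internally for the penalty and the returned
#' weights are back-transformed to per-dosage units. `alpha = 1` is the
#' LASSO, `alpha = 0` ridge regression, anything between an elastic net;
#' `lambda = 0` reduces the objective to OLS and is solved exactly by least
#' squares.
#'
#' @param y complete numeric response (log10 metabolite).
#' @param g a [genotype_matrix()] holding the (clumped) predictor SNPs; may
#'   have zero columns.
#' @param covariates numeric covariate design block or `NULL`.
#' @param alpha elastic-net mixing in `[0, 1]`.
#' @param lambda penalty (>= 0), on the `(1/2n)`-loss scale above.
#' @param metabolite_id identifier stored in the model.
#' @return A `metabolite_model` with per-dosage SNP `weights` (nonzero
#'   entries only) and unpenalized `covariate_coefficients`.
#' @export
fit_penalized_model <- function(y, g, covariates = NULL, alpha, lambda,
                                metabolite_id = "metabolite") {
  stopifnot(inherits(g, "genotype_matrix"))
  if (anyNA(y)) stop("y must be complete for model fitting")
  if (alpha < 0 || alpha > 1) stop("alpha must be in [0, 1]")
  if (lambda < 0) stop("lambda must be >= 0")
  G <- g$dosages
  C <- if (is.null(covariates)) matrix(numeric(0), length(y), 0) else
    as.matrix(covariates)
  fit <- .fit_penalized(y, G, C, alpha, lambda)
  wdf <- data.frame(snp = g$snp_meta$snp,
                    effect_allele = g$snp_meta$a1,
                    other_allele = g$snp_meta$a2,
                    weight = fit$b_snp, stringsAsFactors = FALSE)
  wdf <- wdf[wdf$weight != 0, , drop = FALSE]
  .new_model(metabolite_id, .model_family(alpha), alpha = alpha,
             lambda = lambda, weights = wdf,
             covariate_coefficients = fit$b_other)
}

# Closed-form elastic net for a single penalized predictor and no
# covariates (glmnet requires >= 2 columns): soft-threshold the
# standardized covariance and shrink by the ridge term.
.en_univariate <- function(y, x, alpha, lambda) {
  n <- length(y)
  sdn <- sqrt(mean((x - mean(x))^2))
  if (sdn == 0) return(c(mean(y), 0))
  xs <- (x - mean(x)) / sdn
  rho <- mean(xs * (y - mean(y)))
  b_std <- sign(rho) * max(0, abs(rho) - lambda * alpha) /
    (1 + lambda * (1 - alpha))
  b <- b_std / sdn
  c(mean(y) - b * mean(x), b)
}

# Core penalized solver. Returns per-dosage SNP coefficients and the
# unpenalized block (intercept first). lambda on the (1/2n) objective scale;
# glmnet's penalty.factor rescaling (factors normalized to sum to nvars) is
# compensated so the passed lambda is realized exactly.
.fit_penalized <- function(y, G, C, alpha, lambda) {
  ps <- ncol(G)
  n <- length(y)
  if (ps == 0L) {
    X <- cbind(rep(1, n), C)
    cf <- qr.coef(qr(X), y)
    cf[is.na(cf)] <- 0
    return(list(b_snp = numeric(0), b_other = cf))
  }
  if (lambda == 0) {
    X <- cbind(rep(1, n), G, C)
    cf <- qr.coef(qr(X), y)
    cf[is.na(cf)] <- 0
    return(list(b_snp = cf[2:(ps + 1)], b_other = cf[-(2:(ps + 1))]))
  }
  if (ps == 1L && ncol(C) == 0L) {
    cf <- .en_univariate(y, G[, 1], alpha, lambda)
    return(list(b_snp = cf[2], b_other = cf[1]))
  }
  X <- cbind(G, C)
  pf <- c(rep(1, ps), rep(0, ncol(C)))
  lam_pass <- lambda * ps / ncol(X)
  fit <- glmnet::glmnet(X, y, family = "gaussian", alpha = alpha,
                        lambda = lam_pass, penalty.factor = pf,
                        standardize = TRUE, thresh = 1e-10, maxit = 1e6)
  cf <- as.numeric(stats::coef(fit))
  if (fit$jerr != 0) stop("penalized solver did not converge (jerr=",
                          fit$jerr, ")")
  list(b_snp = cf[2:(ps + 1)], b_other = cf[c(1, seq_len(ncol(C)) + ps + 1)])
}

# Path version: one glmnet call per alpha over the whole lambda grid.
# Returns list(coefs = (1 + ps + pc) x n_lambda matrix aligned to `lambdas`).
.fit_penalized_path <- function(y, G, C, alpha, lambdas) {
  ps <- ncol(G)
  n <- length(y)
  p_all <- 1 + ps + ncol(C)
  out <- matrix(0, p_all, length(lambdas))
  if (ps == 0L) {
    X <- cbind(rep(1, n), C)
    cf <- qr.coef(qr(X), y)
    cf[is.na(cf)] <- 0
    out[c(1, seq_len(ncol(C)) + 1), ] <- cf
    return(out)
  }
  if (ps == 1L && ncol(C) == 0L) {
    for (li in seq_along(lambdas)) {
      out[, li] <- .en_univariate(y, G[, 1], alpha, lambdas[li])
    }
    return(out)
  }
  X <- cbind(G, C)
  pf <- c(rep(1, ps), rep(0, ncol(C)))
  adj <- ps / ncol(X)
  ord <- order(lambdas, decreasing = TRUE)
  fit <- glmnet::glmnet(X, y, family = "gaussian", alpha = alpha,
                        lambda = lambdas[ord] * adj, penalty.factor = pf,
                        standardize = TRUE, thresh = 1e-10, maxit = 1e6)
  cf <- rbind(as.numeric(fit$a0), as.matrix(fit$beta))
  # glmnet may drop path points on failure; map back by position
  if (ncol(cf) != length(lambdas)) {
    stop("penalized path solver returned ", ncol(cf), " of ",
         length(lambdas), " requested grid points")
  }
  out[, ord] <- cf # rows: intercept, snps, covariates
  # reorder rows to intercept, snp block, covariate block (already so)
  out
}

#' Clumping-and-thresholding polygenic score model
#'
#' A weighted allele score over the clumped index SNPs whose GWAS p-value is
#' below `p_threshold`; the weights are the raw GWAS betas.
#'
#' @param clumped output of [ld_clump()] carrying the fold-GWAS `beta` and
#'   `p` of each index SNP.
#' @param g a [genotype_matrix()] (source of allele annotations).
#' @param p_threshold one of the score thresholds (default grid:
#'   1e-4, 1e-3, 1e-2).
#' @param metabolite_id identifier stored in the model.
#' @return A `metabolite_model` of family `"pgs"`. With zero qualifying SNPs
#'   the score is constant and its cross-validated correlation is defined
#'   as 0.
#' @export
fit_polygenic_score <- function(clumped, g, p_threshold,
                                metabolite_id = "metabolite") {
  sel <- clumped[clumped$p < p_threshold, , drop = FALSE]
  idx <- match(sel$snp, g$snp_meta$snp)
  wdf <- data.frame(snp = sel$snp,
                    effect_allele = g$snp_meta$a1[idx],
                    other_allele = g$snp_meta$a2[idx],
                    weight = sel$beta, stringsAsFactors = FALSE)
  .new_model(metabolite_id, "pgs", p_threshold = p_threshold, weights = wdf)
}

#' Predict metabolite levels from a fitted model
#'
#' @param object a `metabolite_model`.
#' @param genotypes a [genotype_matrix()] covering the model SNPs (dosages
#'   are flipped automatically where the stored effect allele is the panel's
#'   other allele).
#' @param covariates covariate design block matching the one used at training
#'   time, or `NULL` to predict the genetic score only.
#' @param ... unused.
#' @return numeric vector of predictions.
#' @export
predict.metabolite_model <- function(object, genotypes, covariates = NULL,
                                     ...) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  n <- nrow(genotypes$dosages)
  score <- numeric(n)
  if (nrow(object$weights) > 0) {
    idx <- match(object$weights$snp, genotypes$snp_meta$snp)
    if (anyNA(idx)) {
      stop("genotypes are missing model SNPs: ",
           paste(object$weights$snp[is.na(idx)], collapse = ", "))
    }
    flip <- .allele_align(object$weights$effect_allele,
                          object$weights$other_allele,
                          genotypes$snp_meta$a1[idx],
                          genotypes$snp_meta$a2[idx])
    if (anyNA(flip)) stop("allele mismatch between model and genotypes")
    d <- genotypes$dosages[, idx, drop = FALSE]
    d[, flip == -1] <- 2 - d[, flip == -1, drop = FALSE]
    score <- as.numeric(d %*% object$weights$weight)
  }
  cc <- object$covariate_coefficients
  if (!is.null(cc) && !is.null(covariates)) {
    C <- as.matrix(covariates)
    score <- score + cc[1] + if (ncol(C) > 0)
      as.numeric(C %*% cc[-1]) else 0
  } else if (!is.null(cc) && is.null(covariates) && length(cc) == 1) {
    score <- score + cc[1]
  }
  score
}

#' @export
coef.metabolite_model <- function(object, ...) {
  stats::setNames(object$weights$weight, object$weights$snp)
}

#' @export
print.metabolite_model <- function(x, ...) {
  cat("metabolite prediction model:", x$metabolite_id, "\n")
  cat("  family:", x$family)
  if (x$family == "pgs") {
    cat(sprintf("  (p threshold %.4g)\n", x$p_threshold))
  } else {
    cat(sprintf("  (alpha %.1f, lambda %.4g)\n", x$alpha, x$lambda))
  }
  cat("  SNPs with nonzero weight:", nrow(x$weights), "\n")
  if (!is.na(x$cv_mean_r)) {
    cat(sprintf("  CV mean r = %.4f  (R2 = %.4f, mean SNPs/fold %.1f)\n",
                x$cv_mean_r, x$cv_r2, x$n_snps_mean))
  }
  invisible(x)
}

.safe_cor <- function(a, b) {
  if (stats::sd(a) == 0 || stats::sd(b) == 0) return(0)
  stats::cor(a, b)
}

#' Fourfold cross-validated model search and selection
#'
#' Runs, within each training fold: a fold-GWAS of the metabolite with
#' covariate control, LD clumping of the fold-GWAS (`r2 < r2_max` within
#' `window_kb`, `p < p_max`), all 121 penalized fits on the 11 x 11
#' `(lambda, alpha)` grid, and the three clumping-and-thresholding polygenic
#' scores; each model's genetic score (SNP weights only — covariate
#' predictability never counts as genetic signal) predicts the held-out
#' portion and the Pearson correlation with the observed values is
#' recorded. The model configuration
#' with the highest mean out-of-fold correlation wins (ties: fewer mean
#' SNPs, then larger lambda) and is refit on the full sample to produce the
#' final weights. Fold-constant predictions count as correlation 0.
#'
#' Held-out data never enter any training stage: fold-GWAS, clumping and
#' fitting see the training portion only, so shuffling a held-out fold's
#' response leaves every fold model bit-identical.
#'
#' @param y metabolite vector (samples with `NA` are dropped up front).
#' @param g a [genotype_matrix()] of training SNPs (combined cohorts).
#' @param covariates numeric covariate design block or `NULL`; computed once
#'   on the combined data and reused across folds.
#' @param folds number of folds (default 4).
#' @param seed seed controlling the fold partition (stratified by cohort so
#'   batch composition stays balanced).
#' @param lambdas,alphas penalized grid (defaults: `10^seq(-5, 0, 0.5)` and
#'   `seq(0, 1, 0.1)`).
#' @param pgs_thresholds polygenic-score p thresholds.
#' @param clump list of clumping parameters (`r2_max`, `window_kb`,
#'   `p_max`).
#' @param ld_panel genotype panel for LD estimation; defaults to the
#'   training-fold genotypes.
#' @param vif_max VIF bound for the fold-GWAS.
#' @param metabolite_id identifier stored in the model.
#' @return The winning `metabolite_model`, refit on all samples, with
#'   `cv_mean_r`, `cv_r2` (square of the mean r) and `n_snps_mean` filled
#'   in. The full grid's CV table is attached as attribute `cv_table`; fold
#'   assignments as `fold_assignment`. Returns a model with family
#'   `"excluded_vif"` if the covariate block breaches the VIF bound in any
#'   fold.
#' @export
cross_validate_and_select <- function(y, g, covariates = NULL, folds = 4L,
                                      seed = 1L,
                                      lambdas = 10^seq(-5, 0, 0.5),
                                      alphas = seq(0, 1, 0.1),
                                      pgs_thresholds = c(1e-4, 1e-3, 1e-2),
                                      clump = list(r2_max = 0.1,
                                                   window_kb = 1000,
                                                   p_max = 0.01),
                                      ld_panel = NULL, vif_max = 50,
                                      metabolite_id = "metabolite") {
  stopifnot(inherits(g, "genotype_matrix"))
  keep <- !is.na(y)
  if (any(!keep)) {
    g <- subset_genotypes(g, samples = which(keep))
    if (!is.null(covariates)) {
      covariates <- as.matrix(covariates)[keep, , drop = FALSE]
    }
    y <- y[keep]
  }
  n <- length(y)
  C <- if (is.null(covariates)) matrix(numeric(0), n, 0) else
    as.matrix(covariates)
  cohort <- if (is.null(g$cohort)) rep("ALL", n) else g$cohort

  set.seed(seed)
  fold_id <- integer(n)
  for (co in unique(cohort)) {
    idx <- which(cohort == co)
    fold_id[idx] <- (sample(seq_along(idx)) %% folds) + 1L
  }

  # config table: penalized grid then PGS thresholds
  grid <- expand.grid(lambda = lambdas, alpha = alphas,
                      KEEP.OUT.ATTRS = FALSE)
  n_pen <- nrow(grid)
  n_cfg <- n_pen + length(pgs_thresholds)
  r_mat <- matrix(NA_real_, n_cfg, folds)
  ns_mat <- matrix(NA_real_, n_cfg, folds)
  fold_models <- vector("list", folds)

  for (f in seq_len(folds)) {
    tr <- fold_id != f
    te <- !tr
    g_tr <- subset_genotypes(g, samples = which(tr))
    C_tr <- C[tr, , drop = FALSE]
    y_tr <- y[tr]
    gw <- run_gwas(g_tr, y_tr, covariates = C_tr, vif_max = vif_max)
    if (isTRUE(attr(gw, "excluded_by_vif"))) {
      m <- .new_model(metabolite_id, "excluded_vif",
                      weights = data.frame(snp = character(0),
                                           effect_allele = character(0),
                                           other_allele = character(0),
                                           weight = numeric(0)))
      return(m)
    }
    panel <- if (is.null(ld_panel)) g_tr else ld_panel
    cl <- ld_clump(gw, panel, r2_max = clump$r2_max,
                   window_kb = clump$window_kb, p_max = clump$p_max)
    snp_idx <- match(cl$snp, g$snp_meta$snp)
    G_tr <- g$dosages[tr, snp_idx, drop = FALSE]
    G_te <- g$dosages[te, snp_idx, drop = FALSE]
    ps <- length(snp_idx)
    fold_models[[f]] <- list(snps = cl$snp, pen = vector("list",
                                                         length(alphas)),
                             pgs = vector("list", length(pgs_thresholds)))

    for (ai in seq_along(alphas)) {
      cf <- .fit_penalized_path(y_tr, G_tr, C_tr, alphas[ai], lambdas)
      fold_models[[f]]$pen[[ai]] <- cf
      # out-of-fold performance of the genetically predicted component:
      # the SNP score only, so covariate predictability never counts as
      # genetic signal (an h2 = 0 metabolite must score r ~ 0)
      pred <- if (ps > 0) {
        G_te %*% cf[1 + seq_len(ps), , drop = FALSE]
      } else matrix(0, sum(te), length(lambdas))
      rows <- (ai - 1L) * length(lambdas) + seq_along(lambdas)
      r_mat[rows, f] <- vapply(seq_along(lambdas), function(li) {
        .safe_cor(pred[, li], y[te])
      }, numeric(1))
      ns_mat[rows, f] <- colSums(cf[1 + seq_len(ps), , drop = FALSE] != 0)
    }
    for (ti in seq_along(pgs_thresholds)) {
      sel <- cl[cl$p < pgs_thresholds[ti], , drop = FALSE]
      fold_models[[f]]$pgs[[ti]] <- sel[, c("snp", "beta")]
      score <- if (nrow(sel) > 0) {
        as.numeric(g$dosages[te, match(sel$snp, g$snp_meta$snp),
                             drop = FALSE] %*% sel$beta)
      } else numeric(sum(te))
      r_mat[n_pen + ti, f] <- .safe_cor(score, y[te])
      ns_mat[n_pen + ti, f] <- nrow(sel)
    }
  }

  cv_tab <- data.frame(
    config = c(sprintf("pen_a%.1f_l%.6g", grid$alpha, grid$lambda),
               sprintf("pgs_%g", pgs_thresholds)),
    family = c(vapply(grid$alpha, .model_family, character(1)),
               rep("pgs", length(pgs_thresholds))),
    alpha = c(grid$alpha, rep(NA_real_, length(pgs_thresholds))),
    lambda = c(grid$lambda, rep(NA_real_, length(pgs_thresholds))),
    p_threshold = c(rep(NA_real_, n_pen), pgs_thresholds),
    mean_r = rowMeans(r_mat),
    n_snps_mean = rowMeans(ns_mat),
    stringsAsFactors = FALSE)

  # winner: max mean r; ties -> fewer mean SNPs -> larger lambda -> grid order
  lam_key <- ifelse(is.na(cv_tab$lambda), -Inf, cv_tab$lambda)
  ord <- order(-cv_tab$mean_r, cv_tab$n_snps_mean, -lam_key,
               seq_len(n_cfg))
  win <- ord[1]

  # final refit on the full sample
  gw_full <- run_gwas(g, y, covariates = C, vif_max = vif_max)
  panel <- if (is.null(ld_panel)) g else ld_panel
  cl_full <- ld_clump(gw_full, panel, r2_max = clump$r2_max,
                      window_kb = clump$window_kb, p_max = clump$p_max)
  g_cl <- subset_genotypes(g, snps = match(cl_full$snp, g$snp_meta$snp))
  model <- if (cv_tab$family[win] == "pgs") {
    fit_polygenic_score(cl_full, g, cv_tab$p_threshold[win],
                        metabolite_id = metabolite_id)
  } else {
    fit_penalized_model(y, g_cl, covariates = C, alpha = cv_tab$alpha[win],
                        lambda = cv_tab$lambda[win],
                        metabolite_id = metabolite_id)
  }
  model$cv_mean_r <- cv_tab$mean_r[win]
  model$cv_r2 <- cv_tab$mean_r[win]^2
  model$n_snps_mean <- cv_tab$n_snps_mean[win]
  attr(model, "cv_table") <- cv_tab
  attr(model, "fold_assignment") <- fold_id
  attr(model, "fold_models") <- fold_models
  model
}

#' Inclusion filter for association testing
#'
#' A model enters the metabolome-wide association stage only when its mean
#' out-of-fold correlation is positive and its predictive R-squared (the
#' square of that mean correlation) exceeds `r2_min`.
#'
#' @param model a `metabolite_model` with CV performance filled in.
#' @param r2_min predictive R-squared threshold (default 0.025).
#' @return logical.
#' @export
model_passes_filter <- function(model, r2_min = 0.025) {
  !is.na(model$cv_mean_r) && model$cv_mean_r > 0 && model$cv_r2 > r2_min
}

#' Restrict genotypes to a clean training set
#'
#' Drops strand-ambiguous SNPs (A/T and C/G pairs, whose orientation cannot
#' be resolved across datasets), SNPs with any missing dosage, and SNPs with
#' MAF below `maf_min` — the requirements for the combined training panel.
#'
#' @param g a [genotype_matrix()].
#' @param maf_min minimum MAF retained (default 0.05; strict `>=`).
#' @return A filtered `genotype_matrix`.
#' @export
prepare_training_genotypes <- function(g, maf_min = 0.05) {
  stopifnot(inherits(g, "genotype_matrix"))
  keep <- !.is_ambiguous(g$snp_meta$a1, g$snp_meta$a2) &
    colSums(is.na(g$dosages)) == 0 &
    g$snp_meta$maf >= maf_min
  subset_genotypes(g, snps = which(keep))
}
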