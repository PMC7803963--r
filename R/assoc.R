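#' Harmonize phenotype GWAS summary statistics to a prediction model
#'
#' Matches every model SNP in the phenotype summary statistics (by SNP id,
#' falling back to `chr:bp` plus the allele pair), orients effects to the
#' model's effect allele (swapped alleles flip the sign; strand complements
#' are resolved by complementing then matching), and drops strand-ambiguous
#' (A/T, C/G) SNPs whose orientation is undecidable. Effect sizes reported
#' as odds ratios are converted with `beta = ln(OR)`; z-only records are
#' converted with the standard approximation
#' `beta = z / sqrt(2 f (1-f) (n + z^2))` (and
#' `se = 1 / sqrt(2 f (1-f) (n + z^2))`), `f` being the effect-allele
#' frequency.
#'
#' @param model a `metabolite_model` (its `weights` define the target SNPs
#'   and effect alleles).
#' @param stats data frame of summary statistics with columns `snp`,
#'   `effect_allele`, `other_allele` and at least one of `beta`, `or`, `z`,
#'   plus `se` (for beta/or records), `p`, `n`, optionally `freq`, `chr`,
#'   `bp`.
#' @param ld_panel optional [genotype_matrix()]; when supplied, observed
#'   non-model SNPs present in both `stats` and the panel are harmonized to
#'   the panel's effect allele and returned too (flag `panel_obs`), which is
#'   what conditional z-score imputation feeds on.
#' @return data frame of class `harmonized_stats`: `snp`, `z`, `beta`, `se`,
#'   `n`, `flag` (`as_is`, `sign_flipped`, `strand_complemented`,
#'   `strand_complemented_flipped`, `panel_obs`, `missing`, `dropped_*`).
#'   Model SNPs missing from `stats` get `NA` statistics and flag
#'   `"missing"`.
#' @export
harmonize_sumstats <- function(model, stats, ld_panel = NULL) {
  stopifnot(inherits(model, "metabolite_model"))
  w <- model$weights
  stats <- as.data.frame(stats)
  if (!all(c("snp", "effect_allele", "other_allele") %in% names(stats))) {
    stop("stats must carry snp, effect_allele, other_allele")
  }
  stats <- .complete_effect_columns(stats)

  harmonize_one <- function(tgt_snp, tgt_a1, tgt_a2, chr = NA, bp = NA) {
    if (.is_ambiguous(tgt_a1, tgt_a2)) {
      return(data.frame(snp = tgt_snp, z = NA_real_, beta = NA_real_,
                        se = NA_real_, n = NA_real_,
                        flag = "dropped_ambiguous", stringsAsFactors = FALSE))
    }
    i <- match(tgt_snp, stats$snp)
    if (is.na(i) && !is.na(chr) && all(c("chr", "bp") %in% names(stats))) {
      cand <- which(stats$chr == chr & stats$bp == bp)
      if (length(cand) == 1) i <- cand
    }
    if (is.na(i)) {
      return(data.frame(snp = tgt_snp, z = NA_real_, beta = NA_real_,
                        se = NA_real_, n = NA_real_, flag = "missing",
                        stringsAsFactors = FALSE))
    }
    a1 <- toupper(stats$effect_allele[i]); a2 <- toupper(stats$other_allele[i])
    flag <- if (a1 == tgt_a1 && a2 == tgt_a2) "as_is"
    else if (a1 == tgt_a2 && a2 == tgt_a1) "sign_flipped"
    else if (.comp_allele(a1) == tgt_a1 && .comp_allele(a2) == tgt_a2)
      "strand_complemented"
    else if (.comp_allele(a1) == tgt_a2 && .comp_allele(a2) == tgt_a1)
      "strand_complemented_flipped"
    else "dropped_mismatch"
    if (flag == "dropped_mismatch") {
      return(data.frame(snp = tgt_snp, z = NA_real_, beta = NA_real_,
                        se = NA_real_, n = NA_real_, flag = flag,
                        stringsAsFactors = FALSE))
    }
    s <- if (flag %in% c("sign_flipped", "strand_complemented_flipped"))
      -1 else 1
    data.frame(snp = tgt_snp, z = s * stats$z[i], beta = s * stats$beta[i],
               se = stats$se[i], n = stats$n[i], flag = flag,
               stringsAsFactors = FALSE)
  }

  rows <- lapply(seq_len(nrow(w)), function(j) {
    harmonize_one(w$snp[j], toupper(w$effect_allele[j]),
                  toupper(w$other_allele[j]))
  })
  out <- do.call(rbind, rows)
  if (nrow(w) > 0 && all(out$flag %in% c("missing", "dropped_ambiguous",
                                         "dropped_mismatch"))) {
    stop("untestable model/phenotype pair: no overlap between model SNPs ",
         "and summary statistics")
  }
  if (!is.null(ld_panel)) {
    extra <- setdiff(intersect(ld_panel$snp_meta$snp, stats$snp), w$snp)
    if (length(extra) > 0) {
      pm <- ld_panel$snp_meta[match(extra, ld_panel$snp_meta$snp), ]
      erows <- lapply(seq_len(nrow(pm)), function(j) {
        r <- harmonize_one(pm$snp[j], toupper(pm$a1[j]), toupper(pm$a2[j]))
        if (!r$flag %in% c("missing", "dropped_ambiguous",
                           "dropped_mismatch")) r$flag <- "panel_obs"
        r
      })
      out <- rbind(out, do.call(rbind, erows))
    }
  }
  class(out) <- c("harmonized_stats", "data.frame")
  attr(out, "model_snps") <- w$snp
  out
}

# Fill beta/se/z triplets from whatever the file provides (beta+se, OR+se,
# or z-only with freq and n).
.complete_effect_columns <- function(stats) {
  if (!"beta" %in% names(stats)) stats$beta <- NA_real_
  if (!"se" %in% names(stats)) stats$se <- NA_real_
  if (!"z" %in% names(stats)) stats$z <- NA_real_
  if ("or" %in% names(stats)) {
    use <- is.na(stats$beta) & !is.na(stats$or)
    stats$beta[use] <- log(stats$or[use])
  }
  zonly <- is.na(stats$beta) & !is.na(stats$z)
  if (any(zonly)) {
    if (!all(c("freq", "n") %in% names(stats))) {
      stop("z-only records need effect-allele frequency and n for ",
           "beta reconstruction")
    }
    f <- stats$freq[zonly]; nn <- stats$n[zonly]; zz <- stats$z[zonly]
    denom <- sqrt(2 * f * (1 - f) * (nn + zz^2))
    stats$beta[zonly] <- zz / denom
    stats$se[zonly] <- 1 / denom
  }
  need_z <- is.na(stats$z) & !is.na(stats$beta) & !is.na(stats$se)
  stats$z[need_z] <- stats$beta[need_z] / stats$se[need_z]
  stats
}

# Ridge-stabilized panel correlation with unit diagonal:
# (R + eps I) / (1 + eps). Keeps single-SNP and uncorrelated cases exact
# while regularising near-singular blocks.
.stabilized_cor <- function(dosages, eps) {
  R <- suppressWarnings(stats::cor(dosages))
  R[is.na(R)] <- 0
  diag(R) <- 1
  (R + diag(eps, ncol(R))) / (1 + eps)
}

.aligned_panel_dosages <- function(ld_panel, snps, effect_alleles,
                                   other_alleles) {
  idx <- match(snps, ld_panel$snp_meta$snp)
  if (anyNA(idx)) {
    stop("LD panel is missing SNPs: ", paste(snps[is.na(idx)], collapse = ", "))
  }
  d <- ld_panel$dosages[, idx, drop = FALSE]
  flip <- .allele_align(effect_alleles, other_alleles,
                        ld_panel$snp_meta$a1[idx], ld_panel$snp_meta$a2[idx])
  if (anyNA(flip)) stop("allele mismatch between model and LD panel")
  d[, flip == -1] <- 2 - d[, flip == -1, drop = FALSE]
  colnames(d) <- snps
  d
}

#' Impute missing association z-scores from LD
#'
#' Conditional-normal (ImpG-style) imputation: for unobserved target SNPs
#' `u` and observed SNPs `o`,
#' `z_u = Sigma_uo (Sigma_oo + eps I)^(-1) z_o`, with SNP-SNP correlations
#' `Sigma` estimated from the LD reference panel. The attached imputation
#' quality `r2_pred = diag(Sigma_uo (Sigma_oo + eps I)^(-1) Sigma_ou)` is
#' the expected squared correlation between the imputed and true z.
#'
#' @param h a `harmonized_stats` (rows flagged `"missing"` are the targets;
#'   every other finite-z row is an observation).
#' @param ld_panel [genotype_matrix()] covering observed and target SNPs;
#'   targets absent from the panel stay missing (flag `dropped_no_panel`).
#' @param ridge_eps ridge constant added to the observed-observed
#'   correlation block (default 0.1).
#' @return The `harmonized_stats` with imputed rows filled in, flagged
#'   `"imputed"`, and an `impute_r2` column.
#' @export
impute_missing_zscores <- function(h, ld_panel, ridge_eps = 0.1) {
  stopifnot(inherits(h, "harmonized_stats"),
            inherits(ld_panel, "genotype_matrix"))
  if (!"impute_r2" %in% names(h)) h$impute_r2 <- NA_real_
  targets <- which(h$flag == "missing")
  if (length(targets) == 0L) return(h)
  obs <- which(!is.na(h$z))
  in_panel <- h$snp %in% ld_panel$snp_meta$snp
  drop <- targets[!in_panel[targets]]
  h$flag[drop] <- "dropped_no_panel"
  if (length(drop) > 0) {
    warning(length(drop), " target SNPs absent from the LD panel; dropped")
  }
  targets <- targets[in_panel[targets]]
  obs <- obs[in_panel[obs]]
  if (length(targets) == 0L) return(h)
  if (length(obs) == 0L) {
    h$z[targets] <- 0
    h$impute_r2[targets] <- 0
    h$flag[targets] <- "imputed"
    return(h)
  }
  all_idx <- c(obs, targets)
  idx_panel <- match(h$snp[all_idx], ld_panel$snp_meta$snp)
  d <- ld_panel$dosages[, idx_panel, drop = FALSE]
  R <- suppressWarnings(stats::cor(d))
  R[is.na(R)] <- 0
  diag(R) <- 1
  no <- length(obs)
  Soo <- R[seq_len(no), seq_len(no), drop = FALSE] +
    diag(ridge_eps, no)
  Suo <- R[no + seq_along(targets), seq_len(no), drop = FALSE]
  Wt <- solve(Soo, t(Suo)) # no x nt
  h$z[targets] <- as.numeric(crossprod(Wt, h$z[obs]))
  h$impute_r2[targets] <- colSums(Wt * t(Suo))
  h$flag[targets] <- "imputed"
  h
}

#' Weighted-score association test from summary statistics
#'
#' The TWAS-style test of an imputed metabolite against a downstream
#' phenotype: with model weights `w` standardized by the panel dosage
#' standard deviations (`w_j~ = w_j * sd_j`), harmonized phenotype z-scores
#' `z`, and the ridge-stabilized panel correlation matrix `R`,
#' `Z = (w~' z) / sqrt(w~' R w~)`, two-sided normal p. With one SNP this
#' reduces to that SNP's own z; scaling all weights by a constant leaves Z
#' unchanged.
#'
#' @param model a `metabolite_model` that passed the inclusion filter (at
#'   least one nonzero weight).
#' @param h `harmonized_stats` covering the model SNPs (impute first if
#'   needed).
#' @param ld_panel [genotype_matrix()] for weight standardization and the
#'   correlation matrix.
#' @param ridge_eps stabilization constant, shared with the imputation step
#'   (default 0.1).
#' @param phenotype_id label stored in the result.
#' @return one-row data frame of class `association_result`:
#'   `metabolite_id`, `phenotype_id`, `z_score`, `p`, `n_snps_used`.
#' @export
badgers_association <- function(model, h, ld_panel, ridge_eps = 0.1,
                                phenotype_id = "phenotype") {
  stopifnot(inherits(model, "metabolite_model"),
            inherits(h, "harmonized_stats"))
  w <- model$weights
  hh <- h[match(w$snp, h$snp), , drop = FALSE]
  use <- !is.na(hh$z) & w$weight != 0
  if (!any(use)) stop("no harmonized SNP with nonzero weight")
  w <- w[use, , drop = FALSE]
  z <- hh$z[use]
  d <- .aligned_panel_dosages(ld_panel, w$snp, w$effect_allele,
                              w$other_allele)
  sds <- apply(d, 2, stats::sd)
  wt <- w$weight * sds
  R <- .stabilized_cor(d, ridge_eps)
  denom2 <- as.numeric(t(wt) %*% R %*% wt)
  if (denom2 <= 0) stop("degenerate weight variance")
  Z <- sum(wt * z) / sqrt(denom2)
  out <- data.frame(metabolite_id = model$metabolite_id,
                    phenotype_id = phenotype_id,
                    z_score = Z, p = 2 * stats::pnorm(-abs(Z)),
                    n_snps_used = length(z), stringsAsFactors = FALSE)
  class(out) <- c("association_result", "data.frame")
  out
}

#' q-values and FDR-significant calls
#'
#' Benjamini-Hochberg step-up q-values, optionally scaled by Storey's
#' null-proportion estimate `pi0 = #(p > lambda) / (m (1 - lambda))` at
#' fixed `lambda = 0.5` (capped at 1). q-values are monotone non-decreasing
#' in p.
#'
#' @param p vector of p-values in (0, 1].
#' @param method `"storey"` (default) or `"bh"` (`pi0 = 1`).
#' @param fdr_cut significance cut on the q-value (default 0.05,
#'   inclusive).
#' @param pi0_lambda Storey tuning constant (default 0.5).
#' @return list: `q` (q-values in input order), `pi0`, `significant`
#'   (logical).
#' @export
compute_qvalues <- function(p, method = c("storey", "bh"), fdr_cut = 0.05,
                            pi0_lambda = 0.5) {
  method <- match.arg(method)
  if (length(p) == 0L) {
    return(list(q = numeric(0), pi0 = NA_real_, significant = logical(0)))
  }
  if (any(is.na(p)) || any(p <= 0) || any(p > 1)) {
    stop("p-values must lie in (0, 1]")
  }
  pi0 <- if (method == "storey") {
    min(1, mean(p > pi0_lambda) / (1 - pi0_lambda))
  } else 1
  q <- pi0 * stats::p.adjust(p, method = "BH")
  q <- pmin(q, 1)
  list(q = q, pi0 = pi0, significant = q <= fdr_cut)
}
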