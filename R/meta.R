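.complement <- c(A = "T", T = "A", C = "G", G = "C")

.comp_allele <- function(a) unname(.complement[toupper(a)])

.is_ambiguous <- function(a1, a2) {
  toupper(a1) == .comp_allele(a2) # A/T or C/G pairs
}

# Align a study's (effect, other) alleles to reference alleles.
# Returns +1 (as is), -1 (swapped: flip the beta), or NA (unresolvable);
# strand complements are resolved before comparison.
.allele_align <- function(ref_a1, ref_a2, a1, a2) {
  ref_a1 <- toupper(ref_a1); ref_a2 <- toupper(ref_a2)
  a1 <- toupper(a1); a2 <- toupper(a2)
  out <- rep(NA_real_, length(a1))
  out[a1 == ref_a1 & a2 == ref_a2] <- 1
  out[a1 == ref_a2 & a2 == ref_a1] <- -1
  todo <- is.na(out)
  if (any(todo)) {
    c1 <- .comp_allele(a1[todo]); c2 <- .comp_allele(a2[todo])
    sub <- rep(NA_real_, sum(todo))
    sub[c1 == ref_a1[todo] & c2 == ref_a2[todo]] <- 1
    sub[c1 == ref_a2[todo] & c2 == ref_a1[todo]] <- -1
    out[todo] <- sub
  }
  out
}

#' Fixed-effect inverse-variance-weighted meta-analysis
#'
#' Combines per-cohort GWAS results for the SNPs present in every study with
#' weights `w_i = 1/se_i^2`: `beta = sum(w b)/sum(w)`,
#' `se = 1/sqrt(sum(w))`, p two-sided normal — the standard-error-weighted
#' scheme of fixed-effect GWAS meta-analysis. Effect alleles are harmonized
#' to the first study before combining (swapped alleles flip the sign;
#' strand complements are resolved; unresolvable allele pairs are dropped).
#'
#' @param results list of two or more `gwas_result` data frames (see
#'   [run_gwas()]).
#' @return data frame of class `meta_result`: `snp`, `chr`, `bp`,
#'   `effect_allele`, `other_allele`, `beta_meta`, `se_meta`, `z_meta`,
#'   `p_meta`, `direction` (one `+`/`-`/`?` character per study),
#'   `n_studies`. SNPs absent from any study, or with a zero/missing se in
#'   all studies, are dropped; the `dropped` attribute lists them with
#'   reasons.
#' @export
ivw_meta <- function(results) {
  if (!is.list(results) || length(results) < 2) {
    stop("ivw_meta needs at least two studies")
  }
  ref <- results[[1]]
  shared <- Reduce(intersect, lapply(results, function(r) r$snp))
  dropped <- data.frame(snp = character(0), reason = character(0),
                        stringsAsFactors = FALSE)
  miss <- setdiff(ref$snp, shared)
  if (length(miss) > 0) {
    dropped <- rbind(dropped, data.frame(snp = miss, reason = "not_in_all",
                                         stringsAsFactors = FALSE))
  }
  ref <- ref[match(shared, ref$snp), , drop = FALSE]
  k <- length(results)
  nsnp <- length(shared)
  B <- SE <- matrix(NA_real_, nsnp, k)
  for (i in seq_len(k)) {
    r <- results[[i]][match(shared, results[[i]]$snp), , drop = FALSE]
    flip <- .allele_align(ref$effect_allele, ref$other_allele,
                          r$effect_allele, r$other_allele)
    B[, i] <- r$beta * flip
    SE[, i] <- r$se
    SE[is.na(flip), i] <- NA
  }
  usable <- !is.na(B) & !is.na(SE) & SE > 0
  complete <- rowSums(usable) == k
  mismatch <- shared[!complete]
  if (length(mismatch) > 0) {
    dropped <- rbind(dropped,
                     data.frame(snp = mismatch, reason = "unusable_in_study",
                                stringsAsFactors = FALSE))
  }
  idx <- which(complete)
  W <- 1 / SE[idx, , drop = FALSE]^2
  sw <- rowSums(W)
  beta <- rowSums(W * B[idx, , drop = FALSE]) / sw
  se <- 1 / sqrt(sw)
  z <- beta / se
  direction <- vapply(idx, function(i) {
    paste(ifelse(is.na(B[i, ]), "?", ifelse(B[i, ] >= 0, "+", "-")),
          collapse = "")
  }, character(1))
  out <- data.frame(snp = shared[idx], chr = ref$chr[idx], bp = ref$bp[idx],
                    effect_allele = ref$effect_allele[idx],
                    other_allele = ref$other_allele[idx],
                    beta_meta = beta, se_meta = se, z_meta = z,
                    p_meta = 2 * stats::pnorm(-abs(z)),
                    direction = direction, n_studies = rep(k, length(idx)),
                    stringsAsFactors = FALSE)
  class(out) <- c("meta_result", "data.frame")
  attr(out, "dropped") <- dropped
  out
}

#' Discovery/replication bookkeeping
#'
#' Identifies discovery-significant SNPs at `disc_alpha / n_metabolites`
#' (genome-wide significance Bonferroni-corrected for the number of
#' metabolites tested), then assesses replication at
#' `0.05 / (number of discovery-significant SNPs)`. A SNP replicates when
#' its replication p-value is below that threshold and (by default) its
#' effect direction agrees with discovery.
#'
#' @param discovery,replication `gwas_result` data frames covering the
#'   tested SNPs.
#' @param disc_alpha base discovery threshold (default genome-wide 5e-8).
#' @param n_metabolites number of metabolites the discovery threshold is
#'   corrected for.
#' @param require_sign_concordance logical; when `FALSE`, replication is
#'   judged on the p-value alone.
#' @return list of class `replication_report`: thresholds, SNP id vectors,
#'   counts and the replicated fraction.
#' @export
assess_replication <- function(discovery, replication, disc_alpha = 5e-8,
                               n_metabolites = 1L,
                               require_sign_concordance = TRUE) {
  disc_thr <- bonferroni_threshold(disc_alpha, n_metabolites)
  sig <- discovery[!is.na(discovery$p) & discovery$p < disc_thr, ,
                   drop = FALSE]
  if (nrow(sig) == 0L) {
    out <- list(discovery_threshold = disc_thr,
                replication_threshold = NA_real_,
                discovery_snps = character(0), replicated_snps = character(0),
                n_discovery = 0L, n_replicated = 0L,
                replicated_fraction = NA_real_)
    class(out) <- "replication_report"
    return(out)
  }
  rep_thr <- bonferroni_threshold(0.05, nrow(sig))
  r <- replication[match(sig$snp, replication$snp), , drop = FALSE]
  flip <- .allele_align(sig$effect_allele, sig$other_allele,
                        r$effect_allele, r$other_allele)
  rep_beta <- r$beta * flip
  ok_p <- !is.na(r$p) & r$p < rep_thr
  ok_sign <- if (require_sign_concordance) {
    !is.na(rep_beta) & sign(rep_beta) == sign(sig$beta)
  } else TRUE
  replicated <- sig$snp[ok_p & ok_sign]
  out <- list(discovery_threshold = disc_thr,
              replication_threshold = rep_thr,
              discovery_snps = sig$snp, replicated_snps = replicated,
              n_discovery = nrow(sig), n_replicated = length(replicated),
              replicated_fraction = length(replicated) / nrow(sig))
  class(out) <- "replication_report"
  out
}

#' @export
print.replication_report <- function(x, ...) {
  cat("replication report\n")
  cat(sprintf("  discovery threshold:   %.3g (%d significant SNPs)\n",
              x$discovery_threshold, x$n_discovery))
  cat(sprintf("  replication threshold: %.3g\n", x$replication_threshold))
  cat(sprintf("  replicated: %d (%.1f%%)\n", x$n_replicated,
              100 * x$replicated_fraction))
  invisible(x)
}
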