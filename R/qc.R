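#' @keywords internal
.qc_report <- function() {
  structure(list(removed_metabolites = data.frame(metabolite = character(0),
                                                  reason = character(0),
                                                  stringsAsFactors = FALSE),
                 removed_samples = character(0),
                 imputed_cells = integer(0),
                 empty_after_filtering = FALSE),
            class = "qc_report")
}

.qc_add_metabolites <- function(report, ids, reason) {
  stopifnot(reason %in% c("nonxeno_miss", "xeno_miss", "zero_iqr",
                          "post_clean_miss"))
  if (length(ids) > 0) {
    report$removed_metabolites <- rbind(
      report$removed_metabolites,
      data.frame(metabolite = ids, reason = reason, stringsAsFactors = FALSE))
  }
  report
}

#' @export
print.qc_report <- function(x, ...) {
  cat("metabolite QC report\n")
  if (nrow(x$removed_metabolites) > 0) {
    tb <- table(x$removed_metabolites$reason)
    cat("  removed metabolites:", nrow(x$removed_metabolites),
        paste0("(", paste(names(tb), tb, sep = ":", collapse = ", "), ")\n"))
  } else cat("  removed metabolites: 0\n")
  cat("  removed samples:", length(x$removed_samples), "\n")
  if (length(x$imputed_cells) > 0) {
    cat("  imputed cells:",
        paste(names(x$imputed_cells), x$imputed_cells, sep = "=",
              collapse = ", "), "\n")
  }
  if (x$empty_after_filtering) cat("  WARNING: matrix empty after filtering\n")
  invisible(x)
}

.merge_reports <- function(a, b) {
  a$removed_metabolites <- rbind(a$removed_metabolites, b$removed_metabolites)
  a$removed_samples <- c(a$removed_samples, b$removed_samples)
  ic <- a$imputed_cells
  for (nm in names(b$imputed_cells)) {
    ic[nm] <- (if (nm %in% names(ic)) ic[nm] else 0L) + b$imputed_cells[nm]
  }
  a$imputed_cells <- ic
  a$empty_after_filtering <- a$empty_after_filtering || b$empty_after_filtering
  a
}

#' Class-specific missingness filters, sample filter, and per-cohort re-check
#'
#' Applies, in order: (1) removal of non-xenobiotic metabolites missing in at
#' least `nonxeno_cut` of samples; (2) removal of xenobiotic metabolites
#' missing in at least `xeno_cut` of samples; (3) removal of samples missing
#' at least `sample_cut` of the remaining metabolites; (4) removal of any
#' metabolite missing at least `post_clean_cut` of either cohort's samples
#' (the re-check that guards per-cohort sample size after subsetting). All
#' thresholds are inclusive (`>=`). Endogenous compounds are expected in most
#' samples, hence their stricter cut; xenobiotics may be genuinely absent and
#' are only dropped when almost never observed.
#'
#' @param m a [metabolite_matrix()].
#' @param nonxeno_cut,xeno_cut,sample_cut,post_clean_cut proportions in
#'   (0, 1].
#' @param recheck logical; set `FALSE` to skip step (4) (e.g. when the
#'   re-check is to be run separately after external sample subsetting, via
#'   [recheck_cohort_missingness()]).
#' @return list `(matrix, report)`.
#' @export
apply_missingness_filters <- function(m, nonxeno_cut = 0.30, xeno_cut = 0.80,
                                      sample_cut = 0.40, post_clean_cut = 0.50,
                                      recheck = TRUE) {
  stopifnot(inherits(m, "metabolite_matrix"))
  cuts <- c(nonxeno_cut, xeno_cut, sample_cut, post_clean_cut)
  if (any(cuts <= 0) || any(cuts > 1)) stop("cuts must lie in (0, 1]")
  report <- .qc_report()

  miss_frac <- colMeans(is.na(m$values))
  drop_nx <- !m$xenobiotic & miss_frac >= nonxeno_cut
  drop_x <- m$xenobiotic & miss_frac >= xeno_cut
  report <- .qc_add_metabolites(report, colnames(m$values)[drop_nx],
                                "nonxeno_miss")
  report <- .qc_add_metabolites(report, colnames(m$values)[drop_x],
                                "xeno_miss")
  keep <- !(drop_nx | drop_x)
  vals <- m$values[, keep, drop = FALSE]
  xeno <- m$xenobiotic[keep]

  samp_miss <- if (ncol(vals) > 0) rowMeans(is.na(vals)) else
    rep(0, nrow(vals))
  drop_s <- samp_miss >= sample_cut
  report$removed_samples <- rownames(vals)[drop_s]
  vals <- vals[!drop_s, , drop = FALSE]
  cohort <- m$cohort[!drop_s]

  out <- metabolite_matrix(vals, xeno, cohort, log_scale = m$log_scale)
  if (recheck) {
    rc <- recheck_cohort_missingness(out, post_clean_cut)
    out <- rc$matrix
    report <- .merge_reports(report, rc$report)
  }
  if (ncol(out$values) == 0L || nrow(out$values) == 0L) {
    report$empty_after_filtering <- TRUE
  }
  list(matrix = out, report = report)
}

#' Per-cohort missingness re-check
#'
#' Removes any metabolite missing at least `post_clean_cut` of the samples of
#' any single cohort, guaranteeing enough observations per cohort to estimate
#' SNP effects. Run after sample subsetting.
#'
#' @param m a [metabolite_matrix()].
#' @param post_clean_cut inclusive per-cohort missingness cut.
#' @return list `(matrix, report)`.
#' @export
recheck_cohort_missingness <- function(m, post_clean_cut = 0.50) {
  stopifnot(inherits(m, "metabolite_matrix"))
  report <- .qc_report()
  drop <- rep(FALSE, ncol(m$values))
  for (co in unique(m$cohort)) {
    rows <- m$cohort == co
    if (!any(rows)) next
    frac <- colMeans(is.na(m$values[rows, , drop = FALSE]))
    drop <- drop | (frac >= post_clean_cut)
  }
  report <- .qc_add_metabolites(report, colnames(m$values)[drop],
                                "post_clean_miss")
  out <- metabolite_matrix(m$values[, !drop, drop = FALSE],
                           m$xenobiotic[!drop], m$cohort,
                           log_scale = m$log_scale)
  if (ncol(out$values) == 0L) report$empty_after_filtering <- TRUE
  list(matrix = out, report = report)
}

#' Remove metabolites with zero interquartile range
#'
#' A metabolite whose observed values have an IQR of exactly 0 carries no
#' usable variation for association testing. The IQR is computed on
#' non-missing values with the linear-interpolation quantile rule
#' (`type = 7`). Metabolites with fewer than two observed values are treated
#' as zero-IQR and removed.
#'
#' @param m a [metabolite_matrix()].
#' @return list `(matrix, report)`.
#' @export
filter_zero_iqr <- function(m) {
  stopifnot(inherits(m, "metabolite_matrix"))
  report <- .qc_report()
  iqr0 <- vapply(seq_len(ncol(m$values)), function(j) {
    v <- m$values[, j]
    v <- v[!is.na(v)]
    if (length(v) < 2L) return(TRUE)
    stats::IQR(v, type = 7) == 0
  }, logical(1))
  report <- .qc_add_metabolites(report, colnames(m$values)[iqr0], "zero_iqr")
  out <- metabolite_matrix(m$values[, !iqr0, drop = FALSE],
                           m$xenobiotic[!iqr0], m$cohort,
                           log_scale = m$log_scale)
  if (ncol(out$values) == 0L) report$empty_after_filtering <- TRUE
  list(matrix = out, report = report)
}

#' Half-minimum imputation of below-detection values
#'
#' Missing non-xenobiotic cells are set to half the minimum observed value of
#' that metabolite within the sample's cohort — the assumption being that the
#' compound was present below the detection limit. Xenobiotic cells are left
#' missing (the compound may genuinely be absent) and are handled
#' complete-case downstream.
#'
#' @param m a [metabolite_matrix()].
#' @return list `(matrix, report)`; the report counts imputed cells per
#'   cohort.
#' @export
impute_half_minimum <- function(m) {
  stopifnot(inherits(m, "metabolite_matrix"))
  report <- .qc_report()
  vals <- m$values
  counts <- integer(0)
  for (co in unique(m$cohort)) {
    rows <- which(m$cohort == co)
    n_imp <- 0L
    for (j in which(!m$xenobiotic)) {
      v <- vals[rows, j]
      nas <- is.na(v)
      if (!any(nas)) next
      obs <- v[!nas]
      if (length(obs) == 0L) {
        stop("metabolite ", colnames(vals)[j], " has no observed values in ",
             "cohort ", co, "; no minimum exists for imputation")
      }
      vals[rows[nas], j] <- 0.5 * min(obs)
      n_imp <- n_imp + sum(nas)
    }
    counts[co] <- n_imp
  }
  report$imputed_cells <- counts
  list(matrix = metabolite_matrix(vals, m$xenobiotic, m$cohort,
                                  log_scale = m$log_scale),
       report = report)
}

#' Log10-transform metabolite abundances
#'
#' Relative abundances are consistently right-skewed; elementwise log10 makes
#' them approximately Gaussian for linear modelling. Missing cells stay
#' missing.
#'
#' @param m a [metabolite_matrix()] on the raw scale.
#' @return A [metabolite_matrix()] with `log_scale = TRUE`.
#' @export
log10_transform <- function(m) {
  stopifnot(inherits(m, "metabolite_matrix"))
  if (m$log_scale) stop("matrix is already log10-transformed")
  bad <- which(!is.na(m$values) & m$values <= 0, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop("non-positive value for metabolite ", colnames(m$values)[bad[1, 2]],
         ", sample ", rownames(m$values)[bad[1, 1]],
         ": cannot log10-transform")
  }
  metabolite_matrix(log10(m$values), m$xenobiotic, m$cohort, log_scale = TRUE)
}

#' Full metabolite QC chain
#'
#' Missingness filters (metabolite-class filters, then sample filter), the
#' zero-IQR filter, the per-cohort missingness re-check, half-minimum
#' imputation within cohort, and the log10 transform, in that order.
#'
#' @param m a raw-scale [metabolite_matrix()].
#' @inheritParams apply_missingness_filters
#' @return list `(matrix, report)` where `matrix` is log10-scale.
#' @export
qc_metabolites <- function(m, nonxeno_cut = 0.30, xeno_cut = 0.80,
                           sample_cut = 0.40, post_clean_cut = 0.50) {
  s1 <- apply_missingness_filters(m, nonxeno_cut, xeno_cut, sample_cut,
                                  post_clean_cut)
  s2 <- filter_zero_iqr(s1$matrix)
  report <- .merge_reports(s1$report, s2$report)
  if (ncol(s2$matrix$values) == 0L) {
    return(list(matrix = s2$matrix, report = report))
  }
  s3 <- impute_half_minimum(s2$matrix)
  report <- .merge_reports(report, s3$report)
  out <- if (s3$matrix$log_scale) s3$matrix else log10_transform(s3$matrix)
  list(matrix = out, report = report)
}
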