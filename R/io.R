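#' Write/read the genotype TSV dialect
#'
#' Columns `snp`, `chr`, `bp`, `a1`, `a2`, `maf`, then one dosage column per
#' sample. Cohort labels, when present, are stored in a companion header
#' line `#cohort` ahead of the table.
#'
#' @param g a [genotype_matrix()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_genotype_tsv <- function(g, path) {
  stopifnot(inherits(g, "genotype_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(g$cohort)) {
    writeLines(paste0("#cohort\t", paste(g$cohort, collapse = "\t")), con)
  }
  tab <- cbind(g$snp_meta[, c("snp", "chr", "bp", "a1", "a2", "maf")],
               as.data.frame(t(g$dosages)))
  utils::write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_genotype_tsv
#' @export
read_genotype_tsv <- function(path) {
  first <- readLines(path, n = 1)
  cohort <- NULL
  skip <- 0L
  if (startsWith(first, "#cohort")) {
    cohort <- strsplit(first, "\t")[[1]][-1]
    skip <- 1L
  }
  tab <- utils::read.table(path, header = TRUE, sep = "\t", skip = skip,
                           stringsAsFactors = FALSE, check.names = FALSE)
  meta <- tab[, c("snp", "chr", "bp", "a1", "a2", "maf")]
  d <- t(as.matrix(tab[, -(1:6), drop = FALSE]))
  colnames(d) <- meta$snp
  genotype_matrix(d, meta, cohort = cohort)
}

#' Read genotypes from a VCF file
#'
#' Convenience reader for VCF input: hard GT calls are converted to effect
#' allele (ALT) dosages. Requires the `vcfR` package.
#'
#' @param path a VCF file (uncompressed or gzipped).
#' @return A [genotype_matrix()] with ALT as the effect allele.
#' @export
read_genotype_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("reading VCF requires the vcfR package")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  dos <- apply(gt, 2, function(col) {
    vapply(strsplit(gsub("\\|", "/", col), "/"), function(a) {
      sum(as.numeric(a)) }, numeric(1))
  })
  fix <- vcfR::getFIX(v)
  ids <- fix[, "ID"]
  ids[is.na(ids) | ids == "."] <- paste0(fix[, "CHROM"], ":",
                                         fix[, "POS"])[is.na(ids) | ids == "."]
  meta <- data.frame(snp = ids, chr = fix[, "CHROM"],
                     bp = as.integer(fix[, "POS"]),
                     a1 = fix[, "ALT"], a2 = fix[, "REF"],
                     stringsAsFactors = FALSE)
  genotype_matrix(t(dos), meta)
}

#' Write/read the metabolite TSV dialect
#'
#' A `sample` and `cohort` column followed by one column per metabolite;
#' the per-metabolite xenobiotic flag travels in a leading `#xenobiotic`
#' header line (0/1 per metabolite).
#'
#' @param m a [metabolite_matrix()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_metabolite_tsv <- function(m, path) {
  stopifnot(inherits(m, "metabolite_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#xenobiotic\t",
                    paste(as.integer(m$xenobiotic), collapse = "\t")), con)
  writeLines(paste0("#log_scale\t", as.integer(m$log_scale)), con)
  tab <- data.frame(sample = rownames(m$values), cohort = m$cohort,
                    m$values, check.names = FALSE)
  utils::write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_metabolite_tsv
#' @export
read_metabolite_tsv <- function(path) {
  lines <- readLines(path, n = 2)
  xeno <- as.logical(as.integer(strsplit(lines[1], "\t")[[1]][-1]))
  log_scale <- as.logical(as.integer(strsplit(lines[2], "\t")[[1]][2]))
  tab <- utils::read.table(path, header = TRUE, sep = "\t", skip = 2,
                           stringsAsFactors = FALSE, check.names = FALSE)
  vals <- as.matrix(tab[, -(1:2), drop = FALSE])
  rownames(vals) <- tab$sample
  metabolite_matrix(vals, xeno, tab$cohort, log_scale = log_scale)
}

#' Write/read summary statistics TSV
#'
#' Columns `snp`, `chr`, `bp`, `effect_allele`, `other_allele`, `freq`,
#' `beta`, `se`, `z`, `p`, `n` (missing ones are tolerated on read).
#'
#' @param stats a sumstats data frame.
#' @param path output file.
#' @return `path` invisibly / the data frame.
#' @export
write_sumstats_tsv <- function(stats, path) {
  utils::write.table(stats, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_sumstats_tsv
#' @export
read_sumstats_tsv <- function(path) {
  out <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  class(out) <- c("gwas_sumstats", "data.frame")
  out
}

#' Write GWAS results in the METAL dialect
#'
#' Columns `MarkerName`, `Allele1`, `Allele2`, `Effect`, `StdErr`,
#' `P-value`, `N` — the exchange format of standard-error-scheme GWAS
#' meta-analysis.
#'
#' @param r a `gwas_result`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_metal_sumstats <- function(r, path) {
  tab <- data.frame(MarkerName = r$snp, Allele1 = r$effect_allele,
                    Allele2 = r$other_allele, Effect = r$beta,
                    StdErr = r$se, `P-value` = r$p, N = r$n_used,
                    check.names = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Serialize prediction models
#'
#' Final models travel as a weights TSV (`metabolite`, `snp`,
#' `effect_allele`, `other_allele`, `weight`) plus a JSON metadata sidecar
#' (family, hyperparameters, CV performance) — the exchange format the
#' association stage consumes.
#'
#' @param models a `metabolite_model` or list of them.
#' @param weights_path,meta_path output files.
#' @return `weights_path`, invisibly.
#' @export
write_models <- function(models, weights_path, meta_path) {
  if (inherits(models, "metabolite_model")) models <- list(models)
  wtab <- do.call(rbind, lapply(models, function(m) {
    if (nrow(m$weights) == 0) return(NULL)
    cbind(metabolite = m$metabolite_id, m$weights)
  }))
  if (is.null(wtab)) {
    wtab <- data.frame(metabolite = character(0), snp = character(0),
                       effect_allele = character(0),
                       other_allele = character(0), weight = numeric(0))
  }
  utils::write.table(wtab, weights_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  meta <- lapply(models, function(m) {
    list(metabolite_id = m$metabolite_id, family = m$family,
         alpha = m$alpha, lambda = m$lambda, p_threshold = m$p_threshold,
         cv_mean_r = m$cv_mean_r, cv_r2 = m$cv_r2,
         n_snps_mean = m$n_snps_mean)
  })
  names(meta) <- vapply(models, function(m) m$metabolite_id, character(1))
  jsonlite::write_json(meta, meta_path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(weights_path)
}

#' @rdname write_models
#' @export
read_models <- function(weights_path, meta_path) {
  wtab <- utils::read.table(weights_path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
  meta <- jsonlite::read_json(meta_path)
  lapply(meta, function(mm) {
    w <- wtab[wtab$metabolite == mm$metabolite_id,
              c("snp", "effect_allele", "other_allele", "weight"),
              drop = FALSE]
    rownames(w) <- NULL
    m <- .new_model(mm$metabolite_id, mm$family,
                    alpha = if (is.null(mm$alpha)) NA_real_ else mm$alpha,
                    lambda = if (is.null(mm$lambda)) NA_real_ else mm$lambda,
                    p_threshold = if (is.null(mm$p_threshold)) NA_real_ else
                      mm$p_threshold,
                    weights = w)
    m$cv_mean_r <- if (is.null(mm$cv_mean_r)) NA_real_ else mm$cv_mean_r
    m$cv_r2 <- if (is.null(mm$cv_r2)) NA_real_ else mm$cv_r2
    m$n_snps_mean <- if (is.null(mm$n_snps_mean)) NA_real_ else
      mm$n_snps_mean
    m
  })
}

#' Serialize the simulation ground truth
#'
#' @param truth a `sim_truth`.
#' @param path JSON output file.
#' @return `path` invisibly / the `sim_truth`.
#' @export
write_truth_json <- function(truth, path) {
  stopifnot(inherits(truth, "sim_truth"))
  obj <- list(
    causal_snps_per_metabolite = lapply(truth$causal_snps_per_metabolite,
                                        function(d) as.list(d)),
    metabolite_phenotype_effect = as.list(truth$metabolite_phenotype_effect),
    phenotype_gwas_n = truth$phenotype_gwas_n)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' @rdname write_truth_json
#' @export
read_truth_json <- function(path) {
  obj <- jsonlite::read_json(path)
  causal <- lapply(obj$causal_snps_per_metabolite, function(d) {
    data.frame(snp = as.character(unlist(d$snp)),
               beta = as.numeric(unlist(d$beta)),
               stringsAsFactors = FALSE)
  })
  eff <- obj$metabolite_phenotype_effect
  structure(list(
    causal_snps_per_metabolite = causal,
    metabolite_phenotype_effect = if (length(eff) > 0)
      stats::setNames(unlist(eff), names(eff)) else NULL,
    phenotype_gwas_n = obj$phenotype_gwas_n), class = "sim_truth")
}

#' Write a QC report as JSON
#'
#' @param report a `qc_report`.
#' @param path JSON output file.
#' @return `path`, invisibly.
#' @export
write_qc_report <- function(report, path) {
  stopifnot(inherits(report, "qc_report"))
  jsonlite::write_json(
    list(removed_metabolites = report$removed_metabolites,
         removed_samples = report$removed_samples,
         imputed_cells = as.list(report$imputed_cells),
         empty_after_filtering = report$empty_after_filtering),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
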