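#' Genotype matrix with SNP metadata
#'
#' Bundles a sample-by-SNP dosage matrix (values in `[0, 2]`, counting copies
#' of the effect allele) with per-SNP metadata. This is the container every
#' association, clumping and LD computation in the package operates on.
#'
#' @param dosages numeric matrix, samples in rows, SNPs in columns. Column
#'   names must match `snp_meta$snp`; row names are sample identifiers.
#' @param snp_meta data frame with columns `snp`, `chr`, `bp` (1-based),
#'   `a1` (effect allele), `a2` (other allele) and optionally `maf`. If `maf`
#'   is absent it is computed as `min(f, 1 - f)` of the effect-allele
#'   frequency `f` observed in `dosages`.
#' @param cohort optional character/factor vector labelling each sample's
#'   cohort; stored alongside the dosages.
#'
#' @return An object of class `genotype_matrix`: a list with elements
#'   `dosages`, `snp_meta` and `cohort`.
#' @export
genotype_matrix <- function(dosages, snp_meta, cohort = NULL) {
  dosages <- as.matrix(dosages)
  snp_meta <- as.data.frame(snp_meta, stringsAsFactors = FALSE)
  req <- c("snp", "chr", "bp", "a1", "a2")
  missing_cols <- setdiff(req, names(snp_meta))
  if (length(missing_cols) > 0L) {
    stop("snp_meta is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  if (ncol(dosages) != nrow(snp_meta)) {
    stop("dosages has ", ncol(dosages), " SNP columns but snp_meta has ",
         nrow(snp_meta), " rows")
  }
  if (anyDuplicated(snp_meta$snp)) stop("duplicate SNP identifiers in snp_meta")
  if (any(snp_meta$bp <= 0)) stop("bp positions must be strictly positive")
  if (length(dosages) > 0 && any(!is.na(dosages))) {
    rng <- range(dosages, na.rm = TRUE)
    if (rng[1] < 0 || rng[2] > 2) stop("dosages must lie in [0, 2]")
  }
  colnames(dosages) <- snp_meta$snp
  if (is.null(rownames(dosages))) {
    rownames(dosages) <- sprintf("S%04d", seq_len(nrow(dosages)))
  }
  if (!("maf" %in% names(snp_meta))) {
    f <- colMeans(dosages, na.rm = TRUE) / 2
    snp_meta$maf <- pmin(f, 1 - f)
  }
  if (!is.null(cohort) && length(cohort) != nrow(dosages)) {
    stop("cohort labels must match the number of samples")
  }
  structure(list(dosages = dosages, snp_meta = snp_meta, cohort = cohort),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", nrow(x$dosages), "samples x", ncol(x$dosages),
      "SNPs\n")
  cat("  chromosomes:", paste(unique(x$snp_meta$chr), collapse = ", "), "\n")
  cat("  MAF range: [", sprintf("%.3f", min(x$snp_meta$maf)), ",",
      sprintf("%.3f", max(x$snp_meta$maf)), "]\n")
  if (!is.null(x$cohort)) {
    tb <- table(x$cohort)
    cat("  cohorts:", paste(names(tb), tb, sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosages)

#' Subset a genotype matrix by samples and/or SNPs
#'
#' @param x a [genotype_matrix()].
#' @param samples row indices (integer/logical/character) to keep.
#' @param snps SNP indices or identifiers to keep.
#' @return A `genotype_matrix` restricted to the selection; `maf` is kept as
#'   annotated (not recomputed on the subset).
#' @export
subset_genotypes <- function(x, samples = NULL, snps = NULL) {
  stopifnot(inherits(x, "genotype_matrix"))
  d <- x$dosages
  meta <- x$snp_meta
  coh <- x$cohort
  if (!is.null(samples)) {
    d <- d[samples, , drop = FALSE]
    if (!is.null(coh)) coh <- coh[samples]
  }
  if (!is.null(snps)) {
    if (is.character(snps)) snps <- match(snps, meta$snp)
    d <- d[, snps, drop = FALSE]
    meta <- meta[snps, , drop = FALSE]
  }
  genotype_matrix(d, meta, cohort = coh)
}

#' Metabolite abundance matrix
#'
#' Sample-by-metabolite relative abundances (median-scaled, unitless) with an
#' explicit missingness representation (`NA` cells), a per-metabolite
#' xenobiotic flag and a per-sample cohort label. Xenobiotic compounds are of
#' external origin (diet, drugs) and may be genuinely absent from a sample;
#' endogenous (non-xenobiotic) compounds are expected in most samples, so
#' their missingness is treated as below-detection-limit censoring.
#'
#' @param values numeric matrix, samples x metabolites; `NA` marks a missing
#'   measurement. Non-missing values must be finite and, before log
#'   transformation, strictly positive.
#' @param xenobiotic logical vector, one flag per metabolite.
#' @param cohort character/factor vector, one label per sample.
#' @param log_scale logical; `TRUE` once values are log10-transformed (the
#'   positivity requirement is then waived).
#' @return An object of class `metabolite_matrix`.
#' @export
metabolite_matrix <- function(values, xenobiotic, cohort,
                              log_scale = FALSE) {
  values <- as.matrix(values)
  if (is.null(colnames(values))) {
    colnames(values) <- sprintf("met%03d", seq_len(ncol(values)))
  }
  if (is.null(rownames(values))) {
    rownames(values) <- sprintf("S%04d", seq_len(nrow(values)))
  }
  if (anyDuplicated(colnames(values))) stop("metabolite identifiers must be unique")
  if (length(xenobiotic) != ncol(values)) {
    stop("xenobiotic flag length must equal the number of metabolites")
  }
  if (length(cohort) != nrow(values)) {
    stop("cohort labels must match the number of samples")
  }
  obs <- values[!is.na(values)]
  if (any(!is.finite(obs))) stop("observed metabolite values must be finite")
  if (!log_scale && length(obs) > 0 && any(obs <= 0)) {
    stop("observed metabolite abundances must be > 0")
  }
  structure(list(values = values,
                 xenobiotic = as.logical(xenobiotic),
                 cohort = as.character(cohort),
                 log_scale = log_scale),
            class = "metabolite_matrix")
}

#' @export
print.metabolite_matrix <- function(x, ...) {
  cat("metabolite_matrix:", nrow(x$values), "samples x", ncol(x$values),
      "metabolites", if (x$log_scale) "(log10 scale)" else "(raw scale)", "\n")
  cat("  xenobiotic:", sum(x$xenobiotic), "of", length(x$xenobiotic), "\n")
  cat("  missing cells:", sum(is.na(x$values)), sprintf(
    "(%.1f%%)\n", 100 * mean(is.na(x$values))))
  invisible(x)
}

#' @export
dim.metabolite_matrix <- function(x) dim(x$values)
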