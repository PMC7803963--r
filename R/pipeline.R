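.pipe_stop <- function(code, stage, msg) {
  stop(structure(class = c("mwas_pipeline_error", "error", "condition"),
                 list(message = sprintf("[%s @ %s] %s", code, stage, msg),
                      call = sys.call(-1), code = code, stage = stage)))
}

#' Pipeline configuration
#'
#' All stage parameters with their standard defaults: 5 PCs, post-GWAS MAF
#' cut 0.05, clumping r2 < 0.1 within 1000 kb at p < 0.01, the 11 x 11
#' penalty grid, polygenic-score thresholds 1e-4/1e-3/1e-2, fourfold CV,
#' model inclusion at predictive R2 > 0.025, FDR 0.05. A single global seed
#' is fanned out to per-stage sub-seeds as `seed + 10 * stage_index`, so
#' toggling stages never changes another stage's stream.
#'
#' @param ... overrides for any default shown in the function definition;
#'   unknown keys are rejected.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    stages = c("simulate", "qc", "gwas", "meta", "train", "assoc", "mr"),
    sim = list(n_samples_per_cohort = c(155L, 136L), n_snps = 600L,
               n_metabolites = 30L, maf_range = c(0.05, 0.5),
               ld_block_size = 10L, ld_rho = 0.8, h2 = 0.3,
               n_causal_snps = 1L, xenobiotic_fraction = 0.15,
               missingness_rates = list(nonxeno = 0.05, xeno = 0.30)),
    phenotype_effect = 0.5,
    phenotype_gwas_n = 10000L,
    qc = list(nonxeno_cut = 0.30, xeno_cut = 0.80, sample_cut = 0.40,
              post_clean_cut = 0.50),
    gwas = list(pcs = 5L, maf_cut = 0.05, vif_max = 50),
    clump = list(r2_max = 0.1, window_kb = 1000, p_max = 0.01),
    grid = list(lambdas = 10^seq(-5, 0, 0.5), alphas = seq(0, 1, 0.1)),
    pgs_thresholds = c(1e-4, 1e-3, 1e-2),
    folds = 4L,
    model_r2_min = 0.025,
    fdr = 0.05,
    ridge_eps = 0.1,
    mr_n_boot = 1000L,
    seed = 1L,
    genotypes_path = NULL, metabolites_path = NULL, covariates_path = NULL,
    sumstats_path = NULL)
  over <- list(...)
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown) > 0) {
    stop("pipeline_config: unknown keys: ", paste(unknown, collapse = ", "))
  }
  for (nm in names(over)) {
    if (is.list(defaults[[nm]]) && is.list(over[[nm]]) &&
        !is.null(names(defaults[[nm]]))) {
      sub_unknown <- setdiff(names(over[[nm]]), names(defaults[[nm]]))
      if (length(sub_unknown) > 0) {
        stop("pipeline_config: unknown keys in '", nm, "': ",
             paste(sub_unknown, collapse = ", "))
      }
      defaults[[nm]][names(over[[nm]])] <- over[[nm]]
    } else {
      defaults[[nm]] <- over[[nm]]
    }
  }
  structure(defaults, class = "pipeline_config")
}

.stage_seed <- function(cfg, stage) {
  idx <- match(stage, c("simulate", "qc", "gwas", "meta", "train", "assoc",
                        "mr"))
  as.integer(cfg$seed + 10L * idx)
}

#' Run the MWAS pipeline end to end
#'
#' Executes the enabled stages in fixed order — simulate, qc, gwas, meta,
#' train, assoc, mr — writing every output file under `out_dir` and
#' returning a manifest with content hashes. No stage reads a downstream
#' stage's output, and rerunning an identical configuration reproduces
#' identical hashes.
#'
#' @param cfg a [pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @return list of class `pipeline_manifest`: per-file md5 hashes plus key
#'   stage summaries (lambda_GC, replication report, model table,
#'   association table, MR results).
#' @export
run_pipeline <- function(cfg, out_dir) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  summaries <- list()
  emit <- function(name) paths[[length(paths) + 1]] <<- file.path(out_dir, name)

  stages <- cfg$stages
  genotypes <- metab <- covar <- truth <- NULL
  pheno_stats <- NULL

  if ("simulate" %in% stages) {
    sc <- do.call(sim_config, c(cfg$sim, list(seed = .stage_seed(cfg, "simulate"))))
    genotypes <- simulate_genotypes(sc)
    sim <- simulate_metabolome(genotypes, sc)
    metab <- sim$metabolites
    covar <- sim$covariates
    truth <- sim$truth
    target <- names(truth$causal_snps_per_metabolite)[
      vapply(truth$causal_snps_per_metabolite, nrow, integer(1)) > 0][1]
    if (!is.na(target)) {
      truth <- plant_phenotype_effect(truth, target, cfg$phenotype_effect,
                                      n = cfg$phenotype_gwas_n)
      pheno_stats <- simulate_phenotype_sumstats(truth, sc)
      write_sumstats_tsv(pheno_stats, file.path(out_dir, "phenotype_sumstats.tsv"))
      emit("phenotype_sumstats.tsv")
    }
    write_genotype_tsv(genotypes, file.path(out_dir, "genotypes.tsv"))
    write_metabolite_tsv(metab, file.path(out_dir, "metabolites.tsv"))
    utils::write.table(covar, file.path(out_dir, "covariates.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_truth_json(truth, file.path(out_dir, "truth.json"))
    emit("genotypes.tsv"); emit("metabolites.tsv")
    emit("covariates.tsv"); emit("truth.json")
  } else {
    if (is.null(cfg$genotypes_path) || !file.exists(cfg$genotypes_path)) {
      .pipe_stop("E_INPUT", "simulate",
                 "no genotypes: enable the simulate stage or set genotypes_path")
    }
    genotypes <- read_genotype_tsv(cfg$genotypes_path)
    metab <- read_metabolite_tsv(cfg$metabolites_path)
    covar <- utils::read.table(cfg$covariates_path, header = TRUE,
                               sep = "\t", stringsAsFactors = FALSE)
    if (!is.null(cfg$sumstats_path)) {
      pheno_stats <- read_sumstats_tsv(cfg$sumstats_path)
    }
  }

  if ("qc" %in% stages) {
    qc <- qc_metabolites(metab, cfg$qc$nonxeno_cut, cfg$qc$xeno_cut,
                         cfg$qc$sample_cut, cfg$qc$post_clean_cut)
    metab <- qc$matrix
    keep <- match(rownames(metab$values), rownames(genotypes$dosages))
    genotypes <- subset_genotypes(genotypes, samples = keep)
    covar <- covar[match(rownames(metab$values), covar$sample), ,
                   drop = FALSE]
    write_qc_report(qc$report, file.path(out_dir, "qc_report.json"))
    write_metabolite_tsv(metab, file.path(out_dir, "metabolites_qc.tsv"))
    emit("qc_report.json"); emit("metabolites_qc.tsv")
    summaries$qc <- qc$report
  }

  cohorts <- unique(metab$cohort)
  gwas_by_cohort <- NULL
  if ("gwas" %in% stages) {
    gwas_by_cohort <- list()
    lambda_tab <- NULL
    for (co in cohorts) {
      rows <- which(metab$cohort == co)
      g_co <- subset_genotypes(genotypes, samples = rows)
      pcs <- compute_genotype_pcs(g_co, k = cfg$gwas$pcs)
      C <- covariate_design(covar[rows, c("age", "sex"), drop = FALSE],
                            pcs = pcs$scores)
      res_co <- list()
      for (met in colnames(metab$values)) {
        r <- run_gwas(g_co, metab$values[rows, met], covariates = C,
                      vif_max = cfg$gwas$vif_max)
        r <- maf_filter(r, cfg$gwas$maf_cut)
        res_co[[met]] <- r
        lambda_tab <- rbind(lambda_tab,
                            data.frame(cohort = co, metabolite = met,
                                       lambda_gc = genomic_inflation(r)))
      }
      gwas_by_cohort[[co]] <- res_co
    }
    pooled_p <- unlist(lapply(gwas_by_cohort, function(l)
      lapply(l, function(r) r$p)))
    summaries$lambda_gc <- list(per_gwas = lambda_tab,
                                pooled = genomic_inflation(pooled_p))
    utils::write.table(lambda_tab, file.path(out_dir, "lambda_gc.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    emit("lambda_gc.tsv")
  }

  meta_results <- NULL
  if ("meta" %in% stages) {
    if (is.null(gwas_by_cohort) || length(cohorts) < 2) {
      .pipe_stop("E_INPUT", "meta", "meta-analysis needs two cohort GWAS")
    }
    meta_results <- list()
    for (met in names(gwas_by_cohort[[1]])) {
      meta_results[[met]] <- ivw_meta(lapply(gwas_by_cohort, `[[`, met))
    }
    n_met <- length(meta_results)
    rep_reports <- lapply(names(meta_results), function(met) {
      assess_replication(gwas_by_cohort[[1]][[met]],
                         gwas_by_cohort[[2]][[met]],
                         disc_alpha = 5e-8, n_metabolites = n_met)
    })
    names(rep_reports) <- names(meta_results)
    summaries$replication <- rep_reports
    meta_tab <- do.call(rbind, lapply(names(meta_results), function(met) {
      cbind(metabolite = met, meta_results[[met]])
    }))
    utils::write.table(meta_tab, file.path(out_dir, "meta_results.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    emit("meta_results.tsv")
  }

  models <- NULL
  if ("train" %in% stages) {
    g_train <- prepare_training_genotypes(genotypes,
                                          maf_min = cfg$gwas$maf_cut)
    pcs <- compute_genotype_pcs(g_train, k = cfg$gwas$pcs)
    C <- covariate_design(
      data.frame(covar[, c("age", "sex")],
                 batch = metab$cohort, stringsAsFactors = FALSE),
      pcs = pcs$scores)
    models <- list()
    for (met in colnames(metab$values)) {
      models[[met]] <- cross_validate_and_select(
        metab$values[, met], g_train, covariates = C, folds = cfg$folds,
        seed = .stage_seed(cfg, "train"),
        lambdas = cfg$grid$lambdas, alphas = cfg$grid$alphas,
        pgs_thresholds = cfg$pgs_thresholds, clump = cfg$clump,
        vif_max = cfg$gwas$vif_max, metabolite_id = met)
    }
    write_models(models, file.path(out_dir, "model_weights.tsv"),
                 file.path(out_dir, "model_meta.json"))
    emit("model_weights.tsv"); emit("model_meta.json")
    summaries$models <- models
  }

  assoc_tab <- NULL
  if ("assoc" %in% stages) {
    if (is.null(pheno_stats)) {
      .pipe_stop("E_INPUT", "assoc", "phenotype summary statistics missing")
    }
    if (is.null(models)) .pipe_stop("E_INPUT", "assoc", "no trained models")
    keep_models <- Filter(function(m) model_passes_filter(m, cfg$model_r2_min) &&
                            nrow(m$weights) > 0, models)
    rows <- lapply(keep_models, function(m) {
      h <- harmonize_sumstats(m, pheno_stats, ld_panel = genotypes)
      h <- impute_missing_zscores(h, genotypes, ridge_eps = cfg$ridge_eps)
      badgers_association(m, h, genotypes, ridge_eps = cfg$ridge_eps,
                          phenotype_id = "phenotype1")
    })
    if (length(rows) > 0) {
      assoc_tab <- do.call(rbind, rows)
      qv <- compute_qvalues(assoc_tab$p, method = "storey",
                            fdr_cut = cfg$fdr)
      assoc_tab$q_value <- qv$q
      assoc_tab$significant <- qv$significant
      bonf <- bonferroni_threshold(0.05,
                                   nrow(assoc_tab) * 1L) # models x phenotypes
      assoc_tab$bonferroni_significant <- assoc_tab$p < bonf
    } else {
      assoc_tab <- data.frame()
    }
    utils::write.table(assoc_tab, file.path(out_dir, "associations.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    emit("associations.tsv")
    summaries$associations <- assoc_tab
  }

  if ("mr" %in% stages) {
    if (is.null(meta_results) || is.null(models) || is.null(pheno_stats)) {
      .pipe_stop("E_INPUT", "mr",
                 "MR needs meta-analysis results, models and phenotype stats")
    }
    cand <- if (!is.null(assoc_tab) && nrow(assoc_tab) > 0) {
      assoc_tab$metabolite_id[assoc_tab$significant]
    } else character(0)
    mr_rows <- lapply(cand, function(met) {
      m <- models[[met]]
      mres <- meta_results[[met]]
      snps <- intersect(m$weights$snp, mres$snp)
      snps <- intersect(snps, pheno_stats$snp)
      if (length(snps) == 0) return(NULL)
      ex <- mres[match(snps, mres$snp), ]
      out <- pheno_stats[match(snps, pheno_stats$snp), ]
      flip <- .allele_align(ex$effect_allele, ex$other_allele,
                            out$effect_allele, out$other_allele)
      ok <- !is.na(flip)
      if (!any(ok)) return(NULL)
      inp <- mr_input(ex$beta_meta[ok], ex$se_meta[ok],
                      out$beta[ok] * flip[ok], out$se[ok], snp = snps[ok])
      cbind(metabolite = met,
            run_mr(inp, n_boot = cfg$mr_n_boot,
                   seed = .stage_seed(cfg, "mr")))
    })
    mr_tab <- do.call(rbind, mr_rows)
    if (is.null(mr_tab)) mr_tab <- data.frame()
    utils::write.table(mr_tab, file.path(out_dir, "mr_results.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    emit("mr_results.tsv")
    summaries$mr <- mr_tab
  }

  hashes <- tools::md5sum(unlist(paths))
  manifest <- list(files = data.frame(file = basename(names(hashes)),
                                      md5 = unname(hashes),
                                      stringsAsFactors = FALSE),
                   summaries = summaries, config_seed = cfg$seed)
  jsonlite::write_json(manifest$files,
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  class(manifest) <- "pipeline_manifest"
  manifest
}

#' @export
print.pipeline_manifest <- function(x, ...) {
  cat("MWAS pipeline manifest (seed", x$config_seed, ")\n")
  cat("  files:\n")
  for (i in seq_len(nrow(x$files))) {
    cat(sprintf("    %-24s %s\n", x$files$file[i], x$files$md5[i]))
  }
  invisible(x)
}
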