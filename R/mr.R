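#' Instrument set for two-sample Mendelian randomization
#'
#' @param beta_exposure,se_exposure per-instrument effect and standard error
#'   on the exposure (metabolite GWAS), harmonized to a common effect
#'   allele.
#' @param beta_outcome,se_outcome effect and standard error on the outcome
#'   (phenotype GWAS), same allele orientation.
#' @param snp optional instrument identifiers.
#' @return data frame of class `mr_input`.
#' @export
mr_input <- function(beta_exposure, se_exposure, beta_outcome, se_outcome,
                     snp = NULL) {
  k <- length(beta_exposure)
  if (k < 1) stop("at least one instrument required")
  if (length(se_exposure) != k || length(beta_outcome) != k ||
      length(se_outcome) != k) stop("instrument vectors must align")
  if (any(se_exposure <= 0) || any(se_outcome <= 0)) {
    stop("standard errors must be positive")
  }
  if (is.null(snp)) snp <- sprintf("iv%03d", seq_len(k))
  out <- data.frame(snp = snp, beta_exposure = beta_exposure,
                    se_exposure = se_exposure, beta_outcome = beta_outcome,
                    se_outcome = se_outcome, stringsAsFactors = FALSE)
  class(out) <- c("mr_input", "data.frame")
  out
}

.mr_result <- function(method, estimate, se, p, n_instruments,
                       egger_intercept = NA_real_, intercept_p = NA_real_) {
  out <- data.frame(method = method, estimate = estimate, se = se, p = p,
                    n_instruments = n_instruments,
                    egger_intercept = egger_intercept,
                    intercept_p = intercept_p, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("mr_result", "data.frame")
  out
}

#' Wald ratio estimator (single instrument)
#'
#' `estimate = beta_outcome / beta_exposure`, with the first-order
#' delta-method standard error `se_outcome / |beta_exposure|` (the exposure
#' uncertainty is ignored, the referenced-package default; set
#' `second_order = TRUE` to add it).
#'
#' @param i an [mr_input()] with exactly one instrument.
#' @param second_order logical; include the exposure-se term in the delta
#'   expansion.
#' @return one-row `mr_result`.
#' @export
wald_ratio <- function(i, second_order = FALSE) {
  stopifnot(inherits(i, "mr_input"))
  if (nrow(i) != 1) stop("wald_ratio requires exactly one instrument")
  bx <- i$beta_exposure; by <- i$beta_outcome
  if (bx == 0) stop("weak/degenerate instrument: beta_exposure is zero")
  est <- by / bx
  se <- if (second_order) {
    sqrt(i$se_outcome^2 / bx^2 + by^2 * i$se_exposure^2 / bx^4)
  } else i$se_outcome / abs(bx)
  .mr_result("wald_ratio", est, se, 2 * stats::pnorm(-abs(est / se)), 1L)
}

#' Inverse-variance-weighted MR estimator
#'
#' Weighted regression of outcome betas on exposure betas through the
#' origin, weights `1/se_outcome^2` — equivalent to inverse-variance
#' pooling of the per-instrument Wald ratios. By default the standard error
#' is inflated multiplicatively when the residual dispersion exceeds 1
#' (random-effects behavior); `fixed_effect = TRUE` disables the scaling.
#' With a single instrument the call defers to [wald_ratio()].
#'
#' @param i an [mr_input()].
#' @param fixed_effect logical.
#' @return one-row `mr_result`.
#' @export
ivw_mr <- function(i, fixed_effect = FALSE) {
  stopifnot(inherits(i, "mr_input"))
  if (nrow(i) == 1) return(wald_ratio(i))
  bx <- i$beta_exposure; by <- i$beta_outcome
  if (all(bx == 0)) stop("all exposure effects are zero")
  w <- 1 / i$se_outcome^2
  est <- sum(w * bx * by) / sum(w * bx^2)
  se <- 1 / sqrt(sum(w * bx^2))
  if (!fixed_effect && nrow(i) > 2) {
    disp <- sum(w * (by - est * bx)^2) / (nrow(i) - 1)
    if (disp > 1) se <- se * sqrt(disp)
  }
  .mr_result("ivw", est, se, 2 * stats::pnorm(-abs(est / se)), nrow(i))
}

#' MR-Egger regression with pleiotropy (intercept) test
#'
#' Weighted least squares of outcome betas on exposure betas with an
#' intercept, weights `1/se_outcome^2`, after orienting every instrument so
#' `beta_exposure >= 0`. The slope estimates the causal effect; a nonzero
#' intercept indicates directional pleiotropy and its two-sided p-value
#' (t distribution, `k - 2` df) is the pleiotropy test. Standard errors are
#' scaled multiplicatively when residual dispersion exceeds 1.
#'
#' @param i an [mr_input()] with at least three instruments.
#' @return one-row `mr_result` with `egger_intercept` and `intercept_p`
#'   filled.
#' @export
egger_mr <- function(i) {
  stopifnot(inherits(i, "mr_input"))
  k <- nrow(i)
  if (k < 3) stop("insufficient instruments for Egger (need >= 3)")
  flip <- ifelse(i$beta_exposure < 0, -1, 1)
  bx <- i$beta_exposure * flip
  by <- i$beta_outcome * flip
  if (stats::sd(bx) == 0) {
    stop("exposure effects are constant: Egger design is collinear")
  }
  w <- 1 / i$se_outcome^2
  fit <- stats::lm(by ~ bx, weights = w)
  sm <- summary(fit)
  disp <- max(1, sm$sigma^2)
  slope <- stats::coef(fit)["bx"]
  slope_se <- sm$coefficients["bx", "Std. Error"] / sm$sigma * sqrt(disp)
  int <- stats::coef(fit)["(Intercept)"]
  int_se <- sm$coefficients["(Intercept)", "Std. Error"] / sm$sigma *
    sqrt(disp)
  .mr_result("egger", unname(slope), unname(slope_se),
             unname(2 * stats::pt(-abs(slope / slope_se), k - 2)), k,
             egger_intercept = unname(int),
             intercept_p = 2 * stats::pt(-abs(int / int_se), k - 2))
}

#' Weighted-median MR estimator
#'
#' Orders the per-instrument Wald ratios and takes the weighted median
#' (linear interpolation at cumulative weight 0.5) under weights
#' proportional to the inverse variance of each ratio — consistent as long
#' as at least half the total weight comes from valid instruments. The
#' standard error is a seeded parametric bootstrap over the instrument
#' betas.
#'
#' @param i an [mr_input()] with at least three instruments.
#' @param n_boot bootstrap resamples (default 1000).
#' @param seed bootstrap seed.
#' @return one-row `mr_result`.
#' @export
weighted_median_mr <- function(i, n_boot = 1000L, seed = 1L) {
  stopifnot(inherits(i, "mr_input"))
  k <- nrow(i)
  if (k < 3) stop("insufficient instruments for the weighted median (>= 3)")
  wm <- function(bx, by, se_y) {
    ratio <- by / bx
    w <- bx^2 / se_y^2 # 1 / var(ratio), first-order
    ord <- order(ratio)
    ratio <- ratio[ord]; w <- w[ord]
    cw <- (cumsum(w) - 0.5 * w) / sum(w)
    if (cw[1] >= 0.5) return(ratio[1])
    if (cw[length(cw)] <= 0.5) return(ratio[length(ratio)])
    below <- max(which(cw < 0.5))
    stats::approx(cw[below + c(0, 1)], ratio[below + c(0, 1)],
                  xout = 0.5)$y
  }
  est <- wm(i$beta_exposure, i$beta_outcome, i$se_outcome)
  set.seed(seed)
  boots <- vapply(seq_len(n_boot), function(b) {
    wm(stats::rnorm(k, i$beta_exposure, i$se_exposure),
       stats::rnorm(k, i$beta_outcome, i$se_outcome), i$se_outcome)
  }, numeric(1))
  se <- stats::sd(boots)
  .mr_result("weighted_median", est, se,
             2 * stats::pnorm(-abs(est / se)), k)
}

#' Run the MR estimator battery on one instrument set
#'
#' One instrument: Wald ratio. Two: IVW only. Three or more: IVW, Egger and
#' weighted median.
#'
#' @param i an [mr_input()].
#' @param n_boot,seed passed to [weighted_median_mr()].
#' @return an `mr_result` data frame with one row per method.
#' @export
run_mr <- function(i, n_boot = 1000L, seed = 1L) {
  stopifnot(inherits(i, "mr_input"))
  k <- nrow(i)
  res <- if (k == 1) {
    wald_ratio(i)
  } else if (k == 2) {
    ivw_mr(i)
  } else {
    rbind(ivw_mr(i), egger_mr(i),
          weighted_median_mr(i, n_boot = n_boot, seed = seed))
  }
  class(res) <- c("mr_result", "data.frame")
  res
}
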