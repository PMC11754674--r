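#' Build a three-way harmonized set for multivariable MR
#'
#' Combines the exposure and mediator instrument sets (union, de-duplicated),
#' clumps the union at the UVMR threshold so no residual LD remains, and
#' harmonizes exposure, mediator and outcome effects to shared effect
#' alleles. Clumping priority ranks each variant by the smaller of its
#' exposure and mediator association p-values.
#'
#' @param exposure_instruments,mediator_instruments Instrument tibbles from
#'   [select_genome_wide()] / [select_cis()].
#' @param exposure,mediator,outcome Summary-statistic tibbles.
#' @param ld LD matrix covering the union of instruments.
#' @param r2 Clumping threshold for the combined set.
#' @return A harmonized tibble with `beta_exp/se_exp`, `beta_med/se_med`,
#'   `beta_out/se_out` columns (see [harmonize()]).
#' @export
build_mvmr_set <- function(exposure_instruments, mediator_instruments,
                           exposure, mediator, outcome, ld, r2 = 0.001) {
  if (nrow(exposure_instruments) == 0 || nrow(mediator_instruments) == 0) {
    abort("both instrument sets must be non-empty")
  }
  ids <- union(exposure_instruments$variant_id, mediator_instruments$variant_id)
  p_exp <- exposure$pval[match(ids, exposure$variant_id)]
  p_med <- mediator$pval[match(ids, mediator$variant_id)]
  rank_p <- pmin(p_exp, p_med, na.rm = TRUE)
  combined <- exposure[match(ids, exposure$variant_id), ]
  combined$pval <- rank_p # clump priority: smaller of the two association p's
  combined <- combined[!is.na(combined$variant_id), , drop = FALSE]
  clumped <- ld_clump(combined, ld, r2_threshold = r2)
  if (nrow(clumped) == 0) {
    abort("empty instrument union after clumping")
  }
  h <- harmonize(exposure[exposure$variant_id %in% clumped$variant_id, ],
                 outcome, mediator = mediator)
  harmonized_effects(h)
}

#' Multivariable IVW Mendelian randomization
#'
#' Weighted least squares of the outcome effects on the exposure and mediator
#' effects without intercept, weights `1/se_out^2`, giving the direct effect
#' of each exposure conditional on the other. Heterogeneity is summarized by
#' the generalized Cochran's Q statistic `Q_a`, computed with per-variant
#' weights that propagate the uncertainty of both exposure effects under a
#' pairwise covariance of zero, and conditional instrument strength by
#' [conditional_f()].
#'
#' Standard errors use multiplicative residual scaling floored at 1, matching
#' the IVW convention. An all-zero effect column is dropped from the fit (its
#' coefficient is `NA`); two non-degenerate collinear columns raise a
#' collinearity error.
#'
#' @param h A three-way harmonized tibble from [build_mvmr_set()].
#' @param kappa_tol Condition-number tolerance for the collinearity check.
#' @return An object of class `mvmr_result` with per-exposure estimates and
#'   standard errors, conditional F-statistics, `Q_a` and its p-value.
#' @export
mvmr_ivw <- function(h, kappa_tol = 1e8) {
  h <- harmonized_effects(h)
  if (!"beta_med" %in% names(h)) abort("h must be a three-way harmonized set")
  k <- nrow(h)
  if (k < 3) {
    abort("mvmr_ivw requires at least 3 variants",
          class = "protscreen_insufficient_snp_error")
  }
  X <- cbind(exposure = h$beta_exp, mediator = h$beta_med)
  w <- 1 / h$se_out^2
  nonzero <- apply(X, 2, function(col) any(col != 0))
  Xf <- X[, nonzero, drop = FALSE]
  if (ncol(Xf) == 0) abort("all effect columns are zero")
  if (ncol(Xf) > 1 && kappa(crossprod(Xf * sqrt(w)), exact = TRUE) > kappa_tol) {
    abort("exposure effect columns are collinear",
          class = "protscreen_collinearity_error")
  }
  fit <- stats::lm.wfit(x = Xf, y = h$beta_out, w = w)
  coefs <- setNames(rep(NA_real_, 2), colnames(X))
  coefs[colnames(Xf)] <- fit$coefficients
  p <- ncol(Xf)
  sigma2 <- sum(w * fit$residuals^2) / (k - p)
  xtwx_inv <- chol2inv(chol(crossprod(Xf * sqrt(w))))
  ses <- setNames(rep(NA_real_, 2), colnames(X))
  ses[colnames(Xf)] <- sqrt(diag(xtwx_inv)) * max(1, sqrt(sigma2))

  th1 <- if (is.na(coefs["exposure"])) 0 else coefs["exposure"]
  th2 <- if (is.na(coefs["mediator"])) 0 else coefs["mediator"]
  resid <- h$beta_out - th1 * h$beta_exp - th2 * h$beta_med
  w_q <- 1 / (h$se_out^2 + th1^2 * h$se_exp^2 + th2^2 * h$se_med^2)
  Q_a <- sum(w_q * resid^2)
  structure(
    list(estimates = coefs, ses = ses,
         ci_low = coefs - qnorm(0.975) * ses,
         ci_high = coefs + qnorm(0.975) * ses,
         pvals = two_sided_p(coefs / ses),
         conditional_F = c(
           exposure = conditional_f(h, "exposure"),
           mediator = conditional_f(h, "mediator")
         ),
         Q_a = Q_a,
         Q_a_pval = pchisq(Q_a, df = k - 2, lower.tail = FALSE),
         n_snp = k,
         exposure = attr(h, "exposure_id") %||% "exposure",
         mediator = attr(h, "mediator_id") %||% "mediator",
         outcome = attr(h, "outcome_id") %||% "outcome",
         data = h),
    class = "mvmr_result"
  )
}

#' @export
print.mvmr_result <- function(x, ...) {
  cat(sprintf("<mvmr_result> %s + %s -> %s (%d SNPs)\n",
              x$exposure, x$mediator, x$outcome, x$n_snp))
  for (nm in names(x$estimates)) {
    cat(sprintf("  %s: %.4g (se %.4g), cond. F = %.3g\n", nm,
                x$estimates[nm], x$ses[nm], x$conditional_F[nm]))
  }
  cat(sprintf("  Q_a = %.3g (p = %.3g)\n", x$Q_a, x$Q_a_pval))
  invisible(x)
}

#' Conditional F-statistic for one exposure in a two-exposure MVMR set
#'
#' Instrument strength for the assessed exposure conditional on the other,
#' from the generalized Cochran's Q of the working model that regresses the
#' assessed exposure's effects on the other's:
#' `Q(delta) = sum((beta_a - delta * beta_b)^2 / (se_a^2 + delta^2 * se_b^2))`
#' minimized over `delta` (pairwise covariance assumed zero). The statistic is
#' `Q_min / (k - 1)` by default; above 10 is conventionally adequate.
#'
#' @param h A three-way harmonized tibble.
#' @param which `"exposure"` or `"mediator"`: the exposure being assessed.
#' @param df_convention Denominator convention, `k - 1` (default) or `k - 2`.
#' @return The conditional F-statistic (non-negative scalar).
#' @export
conditional_f <- function(h, which = c("exposure", "mediator"),
                          df_convention = c("k-1", "k-2")) {
  which <- match.arg(which)
  df_convention <- match.arg(df_convention)
  h <- harmonized_effects(h)
  k <- nrow(h)
  if (k < 3) {
    abort("conditional_f requires at least 3 variants",
          class = "protscreen_insufficient_snp_error")
  }
  if (which == "exposure") {
    ba <- h$beta_exp; sa <- h$se_exp; bb <- h$beta_med; sb <- h$se_med
  } else {
    ba <- h$beta_med; sa <- h$se_med; bb <- h$beta_exp; sb <- h$se_exp
  }
  q_fun <- function(delta) sum((ba - delta * bb)^2 / (sa^2 + delta^2 * sb^2))
  if (all(bb == 0)) {
    q_min <- q_fun(0)
  } else {
    scale <- max(abs(ba)) / max(abs(bb))
    opt <- optimize(q_fun, interval = c(-100, 100) * max(scale, 1))
    if (!is.finite(opt$objective)) {
      abort("conditional-F minimization failed",
            class = "protscreen_numeric_error")
    }
    q_min <- opt$objective
  }
  denom <- if (df_convention == "k-1") k - 1 else k - 2
  q_min / denom
}
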