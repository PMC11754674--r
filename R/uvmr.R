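#' Univariable two-sample Mendelian randomization estimators
#'
#' Given a harmonized set of per-variant exposure/outcome effects, these
#' functions estimate the causal effect of the exposure on the outcome. The
#' main model is the inverse-variance-weighted multiplicative-random-effects
#' estimator ([mr_ivw_mre()]); [mr_wald_ratio()] handles single-SNP
#' instruments, and [mr_egger()], [mr_weighted_median()] and
#' [mr_weighted_mode()] are pleiotropy-robust sensitivity estimators
#' requiring at least three variants.
#'
#' All estimates are on the outcome scale: per normalized SD for continuous
#' outcomes, log-odds for case-control outcomes.
#'
#' @param h A harmonized tibble from [harmonize()]; only rows with complete
#'   effects are used.
#' @return An object of class `mr_result`; use [tidy()] for a one-row tibble.
#' @name uvmr
NULL

new_mr_result <- function(method, estimate, se, pval, n_snp, h,
                          Q = NA_real_, Q_pval = NA_real_,
                          egger_intercept = NA_real_,
                          egger_intercept_se = NA_real_,
                          egger_intercept_pval = NA_real_) {
  z <- qnorm(0.975)
  structure(
    list(method = method, estimate = estimate, se = se,
         ci_low = estimate - z * se, ci_high = estimate + z * se,
         pval = pval, n_snp = n_snp, Q = Q, Q_pval = Q_pval,
         egger_intercept = egger_intercept,
         egger_intercept_se = egger_intercept_se,
         egger_intercept_pval = egger_intercept_pval,
         exposure = attr(h, "exposure_id") %||% "exposure",
         outcome = attr(h, "outcome_id") %||% "outcome",
         data = h),
    class = "mr_result"
  )
}

#' @export
print.mr_result <- function(x, ...) {
  cat(sprintf("<mr_result> %s: %s -> %s\n", x$method, x$exposure, x$outcome))
  cat(sprintf("  estimate %.4g (se %.4g), 95%% CI [%.4g, %.4g], p = %.3g, %d SNP(s)\n",
              x$estimate, x$se, x$ci_low, x$ci_high, x$pval, x$n_snp))
  if (!is.na(x$Q)) {
    cat(sprintf("  heterogeneity Q = %.3g (p = %.3g)\n", x$Q, x$Q_pval))
  }
  if (!is.na(x$egger_intercept)) {
    cat(sprintf("  Egger intercept %.4g (se %.4g, p = %.3g)\n",
                x$egger_intercept, x$egger_intercept_se, x$egger_intercept_pval))
  }
  invisible(x)
}

check_min_snps <- function(h, k_min, method) {
  if (nrow(h) < k_min) {
    abort(sprintf("%s requires at least %d variant(s), got %d",
                  method, k_min, nrow(h)),
          class = "protscreen_insufficient_snp_error")
  }
}

#' @rdname uvmr
#' @export
mr_wald_ratio <- function(h) {
  h <- harmonized_effects(h)
  check_min_snps(h, 1, "wald_ratio")
  if (nrow(h) > 1) abort("wald_ratio expects exactly one variant")
  if (h$beta_exp == 0) {
    abort("degenerate instrument: exposure beta is zero",
          class = "protscreen_degenerate_instrument_error")
  }
  est <- h$beta_out / h$beta_exp
  se <- h$se_out / abs(h$beta_exp) # first-order delta approximation
  new_mr_result("wald", est, se, two_sided_p(est / se), 1L, h)
}

#' @rdname uvmr
#' @param floor_phi Floor the multiplicative overdispersion at 1 (fixed-effects
#'   lower bound)? Default `FALSE`: the pure multiplicative-random-effects
#'   weighted regression.
#' @export
mr_ivw_mre <- function(h, floor_phi = FALSE) {
  h <- harmonized_effects(h)
  check_min_snps(h, 2, "ivw_mre")
  w <- 1 / h$se_out^2
  sxx <- sum(w * h$beta_exp^2)
  theta <- sum(w * h$beta_exp * h$beta_out) / sxx
  k <- nrow(h)
  Q <- sum(w * (h$beta_out - theta * h$beta_exp)^2)
  phi <- Q / (k - 1)
  if (floor_phi) phi <- max(1, phi)
  se <- sqrt(phi / sxx)
  new_mr_result("ivw_mre", theta, se, two_sided_p(theta / se), k, h,
                Q = Q, Q_pval = pchisq(Q, df = k - 1, lower.tail = FALSE))
}

#' @rdname uvmr
#' @export
mr_egger <- function(h) {
  h <- harmonized_effects(h)
  check_min_snps(h, 3, "egger")
  # Egger is not orientation-invariant: fix the convention beta_exp >= 0
  flip <- sign(h$beta_exp) < 0
  bx <- ifelse(flip, -h$beta_exp, h$beta_exp)
  by <- ifelse(flip, -h$beta_out, h$beta_out)
  if (sd(bx) == 0) {
    abort("egger regression is unidentified when all exposure effects are equal",
          class = "protscreen_degenerate_instrument_error")
  }
  w <- 1 / h$se_out^2
  fit <- stats::lm.wfit(x = cbind(intercept = 1, slope = bx), y = by, w = w)
  k <- nrow(h)
  rss <- sum(w * fit$residuals^2)
  sigma <- sqrt(rss / (k - 2))
  xtwx_inv <- chol2inv(chol(crossprod(cbind(1, bx) * sqrt(w))))
  se_unit <- sqrt(diag(xtwx_inv))
  scale <- max(1, sigma) # multiplicative random effects, floored
  slope <- fit$coefficients[["slope"]]
  slope_se <- se_unit[2] * scale
  int <- fit$coefficients[["intercept"]]
  int_se <- se_unit[1] * scale
  p_t <- function(est, se) 2 * pt(-abs(est / se), df = k - 2)
  new_mr_result("egger", slope, slope_se, p_t(slope, slope_se), k, h,
                Q = rss, Q_pval = pchisq(rss, df = k - 2, lower.tail = FALSE),
                egger_intercept = int, egger_intercept_se = int_se,
                egger_intercept_pval = p_t(int, int_se))
}

ratio_stats <- function(h) {
  ratio <- h$beta_out / h$beta_exp
  # first-order delta variance of the per-variant ratio
  var1 <- h$se_out^2 / h$beta_exp^2
  w <- 1 / var1
  list(ratio = ratio, w = w / sum(w))
}

weighted_median_point <- function(ratio, w) {
  ord <- order(ratio)
  r <- ratio[ord]; w <- w[ord] / sum(w)
  s <- cumsum(w) - w / 2
  if (s[1] >= 0.5) return(r[1])
  if (s[length(s)] <= 0.5) return(r[length(r)])
  stats::approx(s, r, xout = 0.5, ties = "ordered")$y
}

weighted_mode_point <- function(ratio, w, phi = 1, n_grid = 512L) {
  w <- w / sum(w)
  s <- sd(ratio); m <- mad(ratio)
  bw <- phi * 0.9 * min(s, m, na.rm = TRUE) * length(ratio)^(-1 / 5)
  if (!is.finite(bw) || bw <= 0) return(ratio[which.max(w)])
  grid <- seq(min(ratio) - 3 * bw, max(ratio) + 3 * bw, length.out = n_grid)
  dens <- colSums(w * outer(ratio, grid, function(r, g) dnorm(g - r, sd = bw)))
  grid[which.max(dens)]
}

# parametric bootstrap over the sampling distributions of (beta_exp, beta_out)
bootstrap_ratio_se <- function(h, point_fun, boot_reps, seed) {
  k <- nrow(h)
  est <- withr_seed(seed, {
    bx <- matrix(rnorm(boot_reps * k, mean = rep(h$beta_exp, each = boot_reps),
                       sd = rep(h$se_exp, each = boot_reps)), nrow = boot_reps)
    by <- matrix(rnorm(boot_reps * k, mean = rep(h$beta_out, each = boot_reps),
                       sd = rep(h$se_out, each = boot_reps)), nrow = boot_reps)
    vapply(seq_len(boot_reps), function(b) {
      ratio <- by[b, ] / bx[b, ]
      w <- bx[b, ]^2 / h$se_out^2
      point_fun(ratio, w)
    }, double(1))
  })
  sd(est)
}

# evaluate expr under a temporary RNG state
withr_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    }
    on.exit({
      if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}

#' @rdname uvmr
#' @param boot_reps Parametric-bootstrap replicates for the standard error.
#' @param seed Seed for the bootstrap (logged for reproducibility).
#' @export
mr_weighted_median <- function(h, boot_reps = 1000, seed = NULL) {
  h <- harmonized_effects(h)
  check_min_snps(h, 3, "weighted_median")
  rs <- ratio_stats(h)
  est <- weighted_median_point(rs$ratio, rs$w)
  se <- bootstrap_ratio_se(h, weighted_median_point, boot_reps, seed)
  new_mr_result("weighted_median", est, se, two_sided_p(est / se), nrow(h), h)
}

#' @rdname uvmr
#' @param phi Bandwidth multiplier for the mode's normal kernel.
#' @export
mr_weighted_mode <- function(h, phi = 1, boot_reps = 1000, seed = NULL) {
  h <- harmonized_effects(h)
  check_min_snps(h, 3, "weighted_mode")
  rs <- ratio_stats(h)
  est <- weighted_mode_point(rs$ratio, rs$w, phi = phi)
  se <- bootstrap_ratio_se(
    h, function(r, w) weighted_mode_point(r, w, phi = phi, n_grid = 128L),
    boot_reps, seed
  )
  new_mr_result("weighted_mode", est, se, two_sided_p(est / se), nrow(h), h)
}

#' Leave-one-out IVW analysis
#'
#' Re-estimates the IVW-MRE model omitting each variant in turn, flagging
#' variants whose omission changes the sign of the estimate.
#'
#' @inheritParams uvmr
#' @return A tibble with one row per omitted variant: the re-estimate, its
#'   standard error and p-value, and `sign_change`.
#' @export
mr_leave_one_out <- function(h) {
  h <- harmonized_effects(h)
  check_min_snps(h, 3, "leave_one_out")
  full <- mr_ivw_mre(h)
  rows <- map(seq_len(nrow(h)), function(i) {
    fit <- mr_ivw_mre(h[-i, , drop = FALSE])
    tibble(omitted = h$variant_id[i], estimate = fit$estimate, se = fit$se,
           pval = fit$pval,
           sign_change = sign(fit$estimate) != sign(full$estimate))
  })
  out <- list_rbind(rows)
  attr(out, "full_estimate") <- full$estimate
  out
}

#' Run every applicable MR model on a harmonized set
#'
#' Dispatches on the number of usable variants: the Wald ratio for a single
#' SNP, IVW-MRE for two or more, plus MR-Egger, weighted median and weighted
#' mode when at least three are available. The first row is the main model
#' (Wald or IVW-MRE).
#'
#' @inheritParams mr_weighted_median
#' @param sensitivity Compute the sensitivity estimators (Egger, median,
#'   mode)? Set `FALSE` to obtain the main model only.
#' @param floor_phi Passed to [mr_ivw_mre()]; `TRUE` floors the
#'   multiplicative overdispersion at 1, which guards the small-k main model
#'   against spuriously tiny standard errors when the ratios agree by chance.
#' @return A tibble of tidied estimates, one row per model.
#' @export
mr_all_models <- function(h, boot_reps = 1000, seed = NULL, sensitivity = TRUE,
                          floor_phi = FALSE) {
  hh <- harmonized_effects(h)
  k <- nrow(hh)
  if (k == 0) {
    abort("no usable variants after harmonization",
          class = "protscreen_insufficient_snp_error")
  }
  fits <- if (k == 1) {
    list(mr_wald_ratio(hh))
  } else {
    list(mr_ivw_mre(hh, floor_phi = floor_phi))
  }
  if (sensitivity && k >= 3) {
    fits <- c(fits, list(
      mr_egger(hh),
      mr_weighted_median(hh, boot_reps = boot_reps, seed = seed),
      mr_weighted_mode(hh, boot_reps = boot_reps,
                       seed = if (is.null(seed)) NULL else seed + 1L)
    ))
  }
  list_rbind(map(fits, tidy))
}

#' Steiger directionality test
#'
#' Compares the variance in the exposure versus the outcome explained by the
#' instruments to assess whether they plausibly act in the assumed direction
#' (exposure to outcome) rather than reflecting reverse causation.
#' Per-variant variance explained is approximated as `z^2 / (z^2 + n)`; for a
#' case-control outcome an effective sample size `4 / (1/n_case + 1/n_control)`
#' replaces `n`. The summed r-squared values are compared on Fisher's z scale.
#'
#' @inheritParams uvmr
#' @param n_exp,n_out Sample sizes of the exposure and outcome GWAS.
#' @param outcome_type,exposure_type `"continuous"` or `"case_control"`.
#' @param case_fraction Fraction of cases in the outcome GWAS (case-control
#'   outcomes only).
#' @param case_fraction_exp Fraction of cases in the exposure GWAS, when the
#'   assessed "exposure" is itself a case-control trait (reverse-direction
#'   screens).
#' @return An object of class `steiger_result` with fields `r2_exposure`,
#'   `r2_outcome`, `correct_direction`, `z`, `pval`.
#' @export
mr_steiger <- function(h, n_exp, n_out,
                       outcome_type = c("continuous", "case_control"),
                       case_fraction = NULL,
                       exposure_type = c("continuous", "case_control"),
                       case_fraction_exp = NULL) {
  outcome_type <- match.arg(outcome_type)
  exposure_type <- match.arg(exposure_type)
  h <- harmonized_effects(h)
  if (n_exp <= 3 || n_out <= 3) {
    abort("sample sizes must exceed 3", class = "protscreen_domain_error")
  }
  eff_n <- function(n, type, cf, side) {
    if (type != "case_control") return(n)
    if (is.null(cf)) {
      abort(paste0("case fraction required for binary ", side))
    }
    4 * n * cf * (1 - cf)
  }
  n_out_eff <- eff_n(n_out, outcome_type, case_fraction, "outcome")
  n_exp <- eff_n(n_exp, exposure_type, case_fraction_exp, "exposure")
  if (n_out_eff <= 3 || n_exp <= 3) {
    abort("non-positive effective sample size",
          class = "protscreen_domain_error")
  }
  z_exp <- h$beta_exp / h$se_exp
  z_out <- h$beta_out / h$se_out
  r2_exp <- sum(z_exp^2 / (z_exp^2 + n_exp))
  r2_out <- sum(z_out^2 / (z_out^2 + n_out_eff))
  r_exp <- sqrt(min(r2_exp, 1 - 1e-12))
  r_out <- sqrt(min(r2_out, 1 - 1e-12))
  z <- (atanh(r_exp) - atanh(r_out)) /
    sqrt(1 / (n_exp - 3) + 1 / (n_out_eff - 3))
  structure(
    list(r2_exposure = r2_exp, r2_outcome = r2_out,
         correct_direction = r2_exp > r2_out, z = z, pval = two_sided_p(z),
         n_snp = nrow(h)),
    class = "steiger_result"
  )
}

#' @export
print.steiger_result <- function(x, ...) {
  cat(sprintf(
    "<steiger_result> r2(exposure) = %.4g, r2(outcome) = %.4g, %s direction (z = %.3g, p = %.3g)\n",
    x$r2_exposure, x$r2_outcome,
    if (x$correct_direction) "correct" else "reversed", x$z, x$pval))
  invisible(x)
}
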