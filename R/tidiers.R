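#' Tidy MR and screening results
#'
#' Broom-style one-row-per-term summaries of the package's fitted objects.
#'
#' @param x A fitted object from this package.
#' @param ... Unused.
#' @return A tibble.
#' @name protscreen-tidiers
NULL

#' @rdname protscreen-tidiers
#' @export
tidy.mr_result <- function(x, ...) {
  tibble(
    exposure = x$exposure, outcome = x$outcome, method = x$method,
    n_snp = x$n_snp, estimate = x$estimate, se = x$se,
    ci_low = x$ci_low, ci_high = x$ci_high, pval = x$pval,
    Q = x$Q, Q_pval = x$Q_pval,
    egger_intercept = x$egger_intercept,
    egger_intercept_se = x$egger_intercept_se,
    egger_intercept_pval = x$egger_intercept_pval
  )
}

#' @rdname protscreen-tidiers
#' @export
glance.mr_result <- function(x, ...) {
  tibble(method = x$method, n_snp = x$n_snp, Q = x$Q, Q_pval = x$Q_pval)
}

#' @rdname protscreen-tidiers
#' @export
tidy.mvmr_result <- function(x, ...) {
  tibble(
    exposure = c(x$exposure, x$mediator),
    term = names(x$estimates),
    outcome = x$outcome,
    estimate = unname(x$estimates), se = unname(x$ses),
    ci_low = unname(x$ci_low), ci_high = unname(x$ci_high),
    pval = unname(x$pvals),
    conditional_F = unname(x$conditional_F),
    n_snp = x$n_snp
  )
}

#' @rdname protscreen-tidiers
#' @export
glance.mvmr_result <- function(x, ...) {
  tibble(n_snp = x$n_snp, Q_a = x$Q_a, Q_a_pval = x$Q_a_pval,
         cond_F_exposure = x$conditional_F[["exposure"]],
         cond_F_mediator = x$conditional_F[["mediator"]])
}

#' @rdname protscreen-tidiers
#' @export
tidy.coloc_result <- function(x, ...) {
  tibble(hypothesis = paste0("h", 0:4),
         posterior = c(x$h0, x$h1, x$h2, x$h3, x$h4),
         n_variants = x$n_variants)
}

#' @rdname protscreen-tidiers
#' @export
glance.coloc_result <- function(x, ...) {
  tibble(h0 = x$h0, h1 = x$h1, h2 = x$h2, h3 = x$h3, h4 = x$h4,
         n_variants = x$n_variants,
         p1 = x$priors$p1, p2 = x$priors$p2, p12 = x$priors$p12)
}

#' @rdname protscreen-tidiers
#' @export
tidy.eff_tests <- function(x, ...) {
  tibble(estimator = c("nyholt", "liji"),
         meff = c(x$meff_nyholt, x$meff_liji),
         used = c(x$meff_nyholt, x$meff_liji) == x$meff_used)
}

#' @rdname protscreen-tidiers
#' @export
glance.eff_tests <- function(x, ...) {
  tibble(m = x$m, meff_nyholt = x$meff_nyholt, meff_liji = x$meff_liji,
         meff_used = x$meff_used, alpha_corrected = x$alpha_corrected)
}

#' @rdname protscreen-tidiers
#' @export
tidy.steiger_result <- function(x, ...) {
  tibble(r2_exposure = x$r2_exposure, r2_outcome = x$r2_outcome,
         correct_direction = x$correct_direction, z = x$z, pval = x$pval,
         n_snp = x$n_snp)
}

#' @rdname protscreen-tidiers
#' @export
tidy.mediation_call <- function(x, ...) {
  tibble(uvmr_estimate = x$uvmr_estimate,
         uvmr_ci_low = x$uvmr_ci[1], uvmr_ci_high = x$uvmr_ci[2],
         mvmr_estimate = x$mvmr_estimate,
         mvmr_ci_low = x$mvmr_ci[1], mvmr_ci_high = x$mvmr_ci[2],
         attenuated = x$attenuated,
         ci_now_overlaps_null = x$ci_now_overlaps_null,
         uvmr_excludes_null = x$uvmr_excludes_null,
         mediation_flag = x$mediation_flag)
}

#' @rdname protscreen-tidiers
#' @export
tidy.screen_result <- function(x, ...) {
  iv <- if (length(x$step_iv)) {
    list_rbind(imap(x$step_iv, function(el, nm) {
      mutate(tidy(el$call), protein = nm, .before = 1)
    }))
  } else {
    tibble(protein = character(0))
  }
  iv
}

#' @rdname protscreen-tidiers
#' @export
glance.screen_result <- function(x, ...) {
  tibble(
    meff = x$eff_tests$meff_used,
    alpha_corrected = x$alpha_corrected,
    step_i_identified = x$step_i$identified,
    n_step_ii_unconflicted = length(x$step_ii$unconflicted),
    n_step_iii_identified = length(x$step_iii$identified),
    n_flagged_mediators = length(x$flagged_mediators)
  )
}
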