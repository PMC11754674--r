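#' Screen configuration
#'
#' Thresholds and tuning parameters for the four-step mediation screen.
#'
#' @param p_genome_wide Genome-wide instrument p-value threshold.
#' @param p_cis cis-pQTL instrument p-value threshold.
#' @param r2 LD-independence (clumping) threshold.
#' @param alpha Family-wise alpha before the effective-tests correction.
#' @param reverse_alpha_step_i Reverse-arm p threshold for step i, whose
#'   forward rule carries no p threshold of its own (nominal 0.05).
#' @param palindrome_eaf_band Harmonization ambiguity band (see
#'   [harmonize()]).
#' @param boot_reps Bootstrap replicates for median/mode standard errors.
#' @param h4_robust,h4_weak Colocalization call (h4 >= `h4_robust`) and
#'   explicit non-corroboration tag (h4 < `h4_weak`).
#' @param z_cap Null-variant cap for the phenotype correlation matrix.
#' @param floor_phi Floor the IVW-MRE overdispersion at 1 inside the screen
#'   (see [mr_ivw_mre()]); the default `TRUE` keeps small-instrument-count
#'   decision arms from producing degenerate standard errors.
#' @param seed Integer seed governing all stochastic components.
#' @return A `screen_config` list.
#' @export
screen_config <- function(p_genome_wide = 5e-8, p_cis = 1.8e-9, r2 = 0.001,
                          alpha = 0.05, reverse_alpha_step_i = 0.05,
                          palindrome_eaf_band = 0.08, boot_reps = 1000,
                          h4_robust = 0.8, h4_weak = 0.5, z_cap = 1.96,
                          floor_phi = TRUE, seed = 1L) {
  structure(as.list(environment()), class = "screen_config")
}

# all point estimates share one nonzero sign
consistent_direction <- function(estimates) {
  estimates <- estimates[!is.na(estimates)]
  if (length(estimates) == 0) return(FALSE)
  all(estimates > 0) || all(estimates < 0)
}

restrict_to <- function(table, ids) {
  out <- table[table$variant_id %in% ids, , drop = FALSE]
  attr(out, "trait_id") <- trait_id(table)
  attr(out, "trait_type") <- trait_type(table)
  out
}

# one MR arm: harmonize instruments against an outcome table, fit the main
# model, and fit the sensitivity models only when asked (they are only
# decision-relevant once the main p-value threshold is met)
mr_arm <- function(instruments, exposure_table, outcome_table, cfg, seed,
                   need_sensitivity = TRUE, p_gate = NULL) {
  if (nrow(instruments) == 0) {
    return(list(testable = FALSE, models = NULL, main = NULL,
                consistent = NA, h = NULL))
  }
  h <- harmonize(restrict_to(exposure_table, instruments$variant_id),
                 outcome_table,
                 palindrome_eaf_band = cfg$palindrome_eaf_band)
  hh <- harmonized_effects(h)
  if (nrow(hh) == 0) {
    return(list(testable = FALSE, models = NULL, main = NULL,
                consistent = NA, h = h))
  }
  main_tbl <- mr_all_models(h, sensitivity = FALSE, floor_phi = cfg$floor_phi)
  main <- main_tbl[1, ]
  gate_open <- is.null(p_gate) || (!is.na(main$pval) && main$pval < p_gate)
  models <- main_tbl
  if (need_sensitivity && gate_open && nrow(hh) >= 3) {
    models <- mr_all_models(h, boot_reps = cfg$boot_reps, seed = seed,
                            floor_phi = cfg$floor_phi)
  }
  list(testable = TRUE, models = models, main = main,
       consistent = consistent_direction(models$estimate), h = h)
}

#' Step i: exposure-outcome association
#'
#' Identifies an exposure-outcome (adiposity-cancer) association: consistent
#' direction of effect across all computable forward MR models, and no
#' consistent reverse signal (reverse models sign-consistent with reverse
#' main p below `reverse_alpha_step_i` counts as a conflict). Steiger
#' directionality is computed and recorded for both arms.
#'
#' @param exposure,outcome Summary-statistic tibbles.
#' @param ld LD matrix or [ld_blocks()].
#' @param config A [screen_config()].
#' @param exposure_instruments,outcome_instruments Optional precomputed
#'   instrument sets (selected genome-wide when omitted).
#' @return A `step_decision` list: `identified`, per-arm model tables,
#'   Steiger results, and an ordered `reasons` rule trace.
#' @export
screen_step_i <- function(exposure, outcome, ld, config = screen_config(),
                          exposure_instruments = NULL,
                          outcome_instruments = NULL) {
  cfg <- config
  exposure_instruments <- exposure_instruments %||%
    select_genome_wide(exposure, ld, cfg$p_genome_wide, cfg$r2)
  outcome_instruments <- outcome_instruments %||%
    suppressWarnings(select_genome_wide(outcome, ld, cfg$p_genome_wide, cfg$r2))
  fwd <- mr_arm(exposure_instruments, exposure, outcome, cfg,
                seed = cfg$seed + 101L)
  if (!fwd$testable) {
    abort("no forward instruments for step i",
          class = "protscreen_empty_instrument_error")
  }
  rev <- mr_arm(outcome_instruments, outcome, exposure, cfg,
                seed = cfg$seed + 102L, p_gate = cfg$reverse_alpha_step_i)
  reasons <- c(sprintf("forward models consistent: %s", fwd$consistent))
  if (rev$testable) {
    rev_conflict <- isTRUE(rev$consistent) &&
      rev$main$pval < cfg$reverse_alpha_step_i
    reasons <- c(reasons, sprintf(
      "reverse consistent: %s; reverse main p = %.3g (threshold %.3g); conflict: %s",
      rev$consistent, rev$main$pval, cfg$reverse_alpha_step_i, rev_conflict))
  } else {
    rev_conflict <- FALSE
    reasons <- c(reasons, "reverse arm untestable (no instruments); forward rule only")
  }
  identified <- isTRUE(fwd$consistent) && !rev_conflict
  out_n <- outcome$n[1]
  cf_out <- if (trait_type(outcome) == "case_control") {
    outcome$n_case[1] / out_n
  } else {
    NULL
  }
  exp_n <- exposure$n[1]
  cf_exp <- if (trait_type(exposure) == "case_control") {
    exposure$n_case[1] / exp_n
  } else {
    NULL
  }
  steiger_fwd <- mr_steiger(fwd$h, n_exp = exp_n, n_out = out_n,
                            outcome_type = trait_type(outcome),
                            case_fraction = cf_out,
                            exposure_type = trait_type(exposure),
                            case_fraction_exp = cf_exp)
  steiger_rev <- if (rev$testable) {
    mr_steiger(rev$h, n_exp = out_n, n_out = exp_n,
               outcome_type = trait_type(exposure),
               case_fraction = cf_exp,
               exposure_type = trait_type(outcome),
               case_fraction_exp = cf_out)
  }
  structure(
    list(step = "i", exposure = trait_id(exposure), outcome = trait_id(outcome),
         identified = identified, forward = fwd$models, reverse = rev$models,
         steiger_forward = steiger_fwd, steiger_reverse = steiger_rev,
         main = fwd$main, reasons = reasons),
    class = "step_decision"
  )
}

#' @export
print.step_decision <- function(x, ...) {
  cat(sprintf("<step_decision> step %s: %s%s -> %s\n", x$step, x$exposure,
              if (!is.null(x$mediator)) paste0(" + ", x$mediator) else "",
              x$outcome))
  cat(sprintf("  identified: %s\n", x$identified))
  for (r in x$reasons) cat("  - ", r, "\n", sep = "")
  invisible(x)
}

#' Step ii: exposure-protein associations with conflict bookkeeping
#'
#' For each protein: the forward (exposure to protein) association is
#' identified when the main-model p-value passes `alpha_corrected` and all
#' computable MR models agree in sign; the reverse association (protein to
#' exposure, using the protein's genome-wide cis+trans instruments) is judged
#' by the same rule. Proteins identified in both directions carry conflicting
#' evidence and are removed: unconflicted = forward minus overlap.
#'
#' @param exposure Summary-statistic tibble for the exposure.
#' @param proteins Named list of protein summary-statistic tibbles.
#' @param ld LD matrix or [ld_blocks()].
#' @param alpha_corrected Effective-tests-corrected p threshold (from
#'   [effective_tests()]).
#' @param config A [screen_config()].
#' @param exposure_instruments Optional precomputed exposure instruments.
#' @param protein_instruments Optional named list of precomputed genome-wide
#'   instrument sets per protein.
#' @return List with `decisions` (per-protein tibble), and the `forward`,
#'   `reverse`, `conflicted`, `unconflicted` protein-id sets.
#' @export
screen_step_ii <- function(exposure, proteins, ld, alpha_corrected,
                           config = screen_config(),
                           exposure_instruments = NULL,
                           protein_instruments = NULL) {
  cfg <- config
  exposure_instruments <- exposure_instruments %||%
    select_genome_wide(exposure, ld, cfg$p_genome_wide, cfg$r2)
  rows <- imap(proteins, function(prot, nm) {
    i <- match(nm, names(proteins))
    fwd <- mr_arm(exposure_instruments, exposure, prot, cfg,
                  seed = cfg$seed + 1000L + i, p_gate = alpha_corrected)
    fwd_pass <- fwd$testable && fwd$main$pval < alpha_corrected &&
      isTRUE(fwd$consistent)
    p_instr <- (protein_instruments %||% list())[[nm]] %||%
      suppressWarnings(select_genome_wide(prot, ld, cfg$p_genome_wide, cfg$r2))
    rev <- mr_arm(p_instr, prot, exposure, cfg,
                  seed = cfg$seed + 2000L + i, p_gate = alpha_corrected)
    rev_pass <- rev$testable && rev$main$pval < alpha_corrected &&
      isTRUE(rev$consistent)
    tibble(
      protein = nm,
      forward_p = if (fwd$testable) fwd$main$pval else NA_real_,
      forward_estimate = if (fwd$testable) fwd$main$estimate else NA_real_,
      forward_consistent = fwd$consistent,
      forward_identified = fwd_pass,
      reverse_p = if (rev$testable) rev$main$pval else NA_real_,
      reverse_consistent = rev$consistent,
      reverse_identified = rev_pass,
      conflicted = fwd_pass && rev_pass,
      unconflicted = fwd_pass && !rev_pass
    )
  })
  decisions <- list_rbind(rows)
  list(
    decisions = decisions,
    forward = decisions$protein[decisions$forward_identified],
    reverse = decisions$protein[decisions$reverse_identified],
    conflicted = decisions$protein[decisions$conflicted],
    unconflicted = decisions$protein[decisions$unconflicted]
  )
}

#' Conflict set logic
#'
#' The step-ii/step-iii bookkeeping rule in isolation: associations identified
#' in both the forward and reverse direction carry conflicting evidence, so
#' the unconflicted set is the forward set minus its overlap with the reverse
#' set.
#'
#' @param forward,reverse Character vectors (or counts via names) of
#'   identified associations in each direction.
#' @return List with `overlap`, `unconflicted`, and their sizes.
#' @export
unconflicted_associations <- function(forward, reverse) {
  overlap <- intersect(forward, reverse)
  unconflicted <- setdiff(forward, overlap)
  list(overlap = overlap, unconflicted = unconflicted,
       n_forward = length(forward), n_reverse = length(reverse),
       n_overlap = length(overlap), n_unconflicted = length(unconflicted))
}

#' Step iii: protein-outcome associations with colocalization corroboration
#'
#' For each protein with cis instruments: the cis-MR association with the
#' outcome must pass `alpha_corrected`; there must be no consistent reverse
#' (outcome to protein) signal at the same threshold; and the colocalization
#' sensitivity grid must return a robust h4 >= 0.8 call. Pairs passing the
#' MR rule but with main-window h4 < 0.5 are explicitly tagged
#' not-corroborated. Proteins without cis instruments are recorded untested.
#'
#' @param proteins Named list of protein summary-statistic tibbles.
#' @param outcome Outcome summary-statistic tibble.
#' @param genes Annotation tibble (`gene_id`, `chrom`, `tss`), one row per
#'   protein, `gene_id` matching the protein names.
#' @param ld LD matrix or [ld_blocks()].
#' @param alpha_corrected Corrected p threshold.
#' @param config A [screen_config()].
#' @param outcome_instruments Optional precomputed outcome instruments.
#' @return List with per-protein `decisions` tibble and identified /
#'   not-corroborated / untested protein-id sets.
#' @export
screen_step_iii <- function(proteins, outcome, genes, ld, alpha_corrected,
                            config = screen_config(),
                            outcome_instruments = NULL) {
  cfg <- config
  outcome_instruments <- outcome_instruments %||%
    suppressWarnings(select_genome_wide(outcome, ld, cfg$p_genome_wide, cfg$r2))
  rows <- imap(proteins, function(prot, nm) {
    i <- match(nm, names(proteins))
    gene <- genes[genes$gene_id == nm, ]
    cis <- if (nrow(gene) == 1) {
      select_cis(prot, gene, ld, cfg$p_cis, r2 = cfg$r2)
    } else {
      prot[0, ]
    }
    base <- tibble(protein = nm, n_cis = nrow(cis), untested = nrow(cis) == 0,
                   forward_p = NA_real_, forward_estimate = NA_real_,
                   reverse_conflict = NA, h4 = NA_real_, coloc_robust = NA,
                   not_corroborated = NA, identified = FALSE)
    if (nrow(cis) == 0) return(base)
    fwd <- mr_arm(cis, prot, outcome, cfg, seed = cfg$seed + 3000L + i,
                  need_sensitivity = FALSE)
    if (!fwd$testable) return(base)
    base$forward_p <- fwd$main$pval
    base$forward_estimate <- fwd$main$estimate
    base$untested <- FALSE
    pass_p <- fwd$main$pval < alpha_corrected
    if (!pass_p) return(base)
    rev <- mr_arm(outcome_instruments, outcome, prot, cfg,
                  seed = cfg$seed + 4000L + i, p_gate = alpha_corrected)
    rev_conflict <- rev$testable && isTRUE(rev$consistent) &&
      rev$main$pval < alpha_corrected
    base$reverse_conflict <- rev_conflict
    lead <- cis$variant_id[which.min(cis$pval)]
    grid <- coloc_sensitivity_grid(prot, outcome, lead,
                                   h4_threshold = cfg$h4_robust)
    base$h4 <- attr(grid, "main_h4")
    base$coloc_robust <- attr(grid, "robust")
    base$not_corroborated <- !is.na(base$h4) && base$h4 < cfg$h4_weak
    base$identified <- pass_p && !rev_conflict && isTRUE(base$coloc_robust)
    base
  })
  decisions <- list_rbind(rows)
  list(
    decisions = decisions,
    identified = decisions$protein[decisions$identified],
    not_corroborated = decisions$protein[!is.na(decisions$not_corroborated) &
                                           decisions$not_corroborated],
    untested = decisions$protein[decisions$untested]
  )
}

#' Colocalization corroboration set logic
#'
#' The step-iii bookkeeping rule in isolation: of the pairs passing the
#' cis-MR threshold, those not corroborated by colocalization (h4 below the
#' weak-evidence cutoff) are removed.
#'
#' @param uvmr_pass Tibble with columns `pair` and `h4` for pairs passing the
#'   cis-MR threshold.
#' @param h4_weak Non-corroboration cutoff (default 0.5).
#' @return List with `identified` pairs and counts.
#' @export
corroborated_associations <- function(uvmr_pass, h4_weak = 0.5) {
  not_cor <- uvmr_pass$pair[uvmr_pass$h4 < h4_weak]
  identified <- setdiff(uvmr_pass$pair, not_cor)
  list(identified = identified, not_corroborated = not_cor,
       n_uvmr = nrow(uvmr_pass), n_not_corroborated = length(not_cor),
       n_identified = length(identified))
}

#' Step iv: mediation call from UVMR and MVMR estimates
#'
#' A protein is flagged as a potential mediator when adjusting for it in MVMR
#' attenuates the exposure-outcome estimate toward the null AND the adjusted
#' 95% CI now overlaps the null, while the unadjusted (UVMR) CI excluded it.
#' Estimates are compared on the log-odds scale; odds ratios are accepted via
#' `scale = "or"`.
#'
#' @param uvmr_estimate,uvmr_ci_low,uvmr_ci_high Unadjusted exposure-outcome
#'   estimate and 95% CI.
#' @param mvmr_estimate,mvmr_ci_low,mvmr_ci_high Protein-adjusted direct
#'   estimate and 95% CI.
#' @param scale `"log_odds"` (default) or `"or"`.
#' @return A `mediation_call` list with `attenuated`,
#'   `ci_now_overlaps_null`, `uvmr_excludes_null` and `mediation_flag`.
#' @export
mediation_call <- function(uvmr_estimate, uvmr_ci_low, uvmr_ci_high,
                           mvmr_estimate, mvmr_ci_low, mvmr_ci_high,
                           scale = c("log_odds", "or")) {
  scale <- match.arg(scale)
  if (scale == "or") {
    vals <- log(c(uvmr_estimate, uvmr_ci_low, uvmr_ci_high,
                  mvmr_estimate, mvmr_ci_low, mvmr_ci_high))
  } else {
    vals <- c(uvmr_estimate, uvmr_ci_low, uvmr_ci_high,
              mvmr_estimate, mvmr_ci_low, mvmr_ci_high)
  }
  u <- vals[1:3]; m <- vals[4:6]
  attenuated <- abs(m[1]) < abs(u[1])
  ci_now_overlaps_null <- m[2] <= 0 && m[3] >= 0
  uvmr_excludes_null <- u[2] > 0 || u[3] < 0
  structure(
    list(uvmr_estimate = u[1], uvmr_ci = u[2:3],
         mvmr_estimate = m[1], mvmr_ci = m[2:3],
         attenuated = attenuated,
         ci_now_overlaps_null = ci_now_overlaps_null,
         uvmr_excludes_null = uvmr_excludes_null,
         mediation_flag = attenuated && ci_now_overlaps_null &&
           uvmr_excludes_null),
    class = "mediation_call"
  )
}

#' @export
print.mediation_call <- function(x, ...) {
  cat(sprintf(
    "<mediation_call> UVMR %.3f [%.3f, %.3f] -> MVMR %.3f [%.3f, %.3f]\n",
    x$uvmr_estimate, x$uvmr_ci[1], x$uvmr_ci[2],
    x$mvmr_estimate, x$mvmr_ci[1], x$mvmr_ci[2]))
  cat(sprintf("  attenuated: %s; adjusted CI overlaps null: %s; flag: %s\n",
              x$attenuated, x$ci_now_overlaps_null, x$mediation_flag))
  invisible(x)
}

#' Run the full four-step mediation screen
#'
#' Executes steps i-iv over a study (the output of [simulate_study()], or any
#' list with the same shape: `tables` holding an `exposure` table, protein
#' tables and an `outcome` table; `ld`; `genes`): effective-tests correction
#' over the protein panel, the exposure-outcome association test, the
#' exposure-protein conflict screen, the cis-MR plus colocalization
#' protein-outcome screen, and MVMR mediation calls for triples that pass
#' with a sign pattern consistent with mediation. Fully deterministic given
#' `config$seed`.
#'
#' @param study List with `tables`, `ld`, `genes` as above.
#' @param config A [screen_config()].
#' @return An object of class `screen_result`: per-step decision tables, the
#'   effective-tests object, mediation calls, and a rule-trace tibble.
#' @export
run_screen <- function(study, config = screen_config()) {
  cfg <- config
  tables <- study$tables
  ld <- study$ld
  prot_names <- setdiff(names(tables), c("exposure", "outcome"))
  proteins <- tables[prot_names]

  eff <- effective_tests(estimate_pheno_corr(proteins, z_cap = cfg$z_cap))
  alpha_c <- eff$alpha_corrected

  exp_instr <- select_genome_wide(tables$exposure, ld, cfg$p_genome_wide, cfg$r2)
  out_instr <- suppressWarnings(
    select_genome_wide(tables$outcome, ld, cfg$p_genome_wide, cfg$r2))

  s1 <- screen_step_i(tables$exposure, tables$outcome, ld, cfg,
                      exposure_instruments = exp_instr,
                      outcome_instruments = out_instr)
  s2 <- screen_step_ii(tables$exposure, proteins, ld, alpha_c, cfg,
                       exposure_instruments = exp_instr)
  s3 <- screen_step_iii(proteins, tables$outcome, study$genes, ld, alpha_c,
                        cfg, outcome_instruments = out_instr)

  candidates <- intersect(s2$unconflicted, s3$identified)
  calls <- list()
  trace <- list()
  for (nm in candidates) {
    a_hat <- s2$decisions$forward_estimate[s2$decisions$protein == nm]
    g_hat <- s3$decisions$forward_estimate[s3$decisions$protein == nm]
    t_hat <- s1$main$estimate
    sign_ok <- s1$identified && !is.na(a_hat) && !is.na(g_hat) &&
      sign(a_hat) * sign(g_hat) == sign(t_hat)
    if (!sign_ok) {
      trace[[nm]] <- tibble(
        step = "iv", protein = nm, outcome = trait_id(tables$outcome),
        note = "rejected: sign pattern inconsistent with mediation (or step i not identified)")
      next
    }
    p_instr <- suppressWarnings(
      select_genome_wide(proteins[[nm]], ld, cfg$p_genome_wide, cfg$r2))
    h3w <- build_mvmr_set(exp_instr, p_instr, tables$exposure,
                          proteins[[nm]], tables$outcome, ld, r2 = cfg$r2)
    mv <- mvmr_ivw(h3w)
    call <- mediation_call(
      s1$main$estimate, s1$main$ci_low, s1$main$ci_high,
      mv$estimates[["exposure"]], mv$ci_low[["exposure"]],
      mv$ci_high[["exposure"]]
    )
    calls[[nm]] <- list(protein = nm, mvmr = mv, call = call)
    trace[[nm]] <- tibble(
      step = "iv", protein = nm, outcome = trait_id(tables$outcome),
      note = sprintf(
        "uvmr %.4f [%.4f, %.4f]; mvmr %.4f [%.4f, %.4f]; attenuated %s; overlaps null %s; flag %s",
        call$uvmr_estimate, call$uvmr_ci[1], call$uvmr_ci[2],
        call$mvmr_estimate, call$mvmr_ci[1], call$mvmr_ci[2],
        call$attenuated, call$ci_now_overlaps_null, call$mediation_flag))
  }
  flagged <- names(keep(calls, function(x) x$call$mediation_flag))
  structure(
    list(eff_tests = eff, alpha_corrected = alpha_c,
         step_i = s1, step_ii = s2, step_iii = s3,
         step_iv = calls, flagged_mediators = flagged,
         trace = if (length(trace)) list_rbind(trace) else
           tibble(step = character(0), protein = character(0),
                  outcome = character(0), note = character(0)),
         config = cfg),
    class = "screen_result"
  )
}

#' @export
print.screen_result <- function(x, ...) {
  cat("<screen_result>\n")
  cat(sprintf("  effective tests: meff = %.1f -> alpha = %.3g\n",
              x$eff_tests$meff_used, x$alpha_corrected))
  cat(sprintf("  step i identified: %s\n", x$step_i$identified))
  cat(sprintf("  step ii unconflicted proteins: %d\n",
              length(x$step_ii$unconflicted)))
  cat(sprintf("  step iii identified proteins: %d\n",
              length(x$step_iii$identified)))
  cat(sprintf("  step iv flagged mediators: %s\n",
              if (length(x$flagged_mediators)) {
                paste(x$flagged_mediators, collapse = ", ")
              } else "none"))
  invisible(x)
}
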