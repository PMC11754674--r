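#' Write screen results to disk
#'
#' Serializes a [run_screen()] result as tab-separated tables plus a
#' machine-readable run log: `step_i_models.tsv` (forward and reverse model
#' estimates), `step_ii_decisions.tsv`, `step_iii_decisions.tsv`,
#' `step_iv_calls.tsv`, `decisions.tsv` (the rule trace), and `run.json`
#' (package version, seed, thresholds, counts).
#'
#' @param res A `screen_result`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_screen_results <- function(res, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(x, name) {
    readr::write_tsv(x, file.path(dir, name), na = "NA", progress = FALSE)
  }
  s1 <- bind_rows(
    mutate(res$step_i$forward, direction = "forward"),
    if (!is.null(res$step_i$reverse)) {
      mutate(res$step_i$reverse, direction = "reverse")
    }
  )
  w(s1, "step_i_models.tsv")
  w(res$step_ii$decisions, "step_ii_decisions.tsv")
  w(res$step_iii$decisions, "step_iii_decisions.tsv")
  iv <- tidy(res)
  w(iv, "step_iv_calls.tsv")
  w(res$trace, "decisions.tsv")
  cfg <- res$config
  run <- list(
    package = "protscreen",
    version = as.character(utils::packageVersion("protscreen")),
    seed = cfg$seed,
    thresholds = list(
      p_genome_wide = cfg$p_genome_wide, p_cis = cfg$p_cis, r2 = cfg$r2,
      alpha = cfg$alpha, alpha_corrected = res$alpha_corrected,
      reverse_alpha_step_i = cfg$reverse_alpha_step_i,
      h4_robust = cfg$h4_robust, h4_weak = cfg$h4_weak
    ),
    meff = list(m = res$eff_tests$m,
                nyholt = res$eff_tests$meff_nyholt,
                liji = res$eff_tests$meff_liji,
                used = res$eff_tests$meff_used),
    counts = as.list(glance(res))
  )
  jsonlite::write_json(run, file.path(dir, "run.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}
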