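# a hand-built two-trait study where effects flow in both directions:
# exposure instruments e1..e4 all raise the outcome; outcome instruments
# o1..o4 all raise the exposure (strongly and precisely)
bidirectional_tables <- function() {
  ids_e <- sprintf("e%d", 1:4)
  ids_o <- sprintf("o%d", 1:4)
  bx <- c(0.10, 0.12, 0.15, 0.20)
  bo <- c(0.10, 0.12, 0.15, 0.20)
  exposure <- make_table(tibble::tibble(
    variant_id = c(ids_e, ids_o),
    pos = seq(1e6, by = 1e6, length.out = 8),
    beta = c(bx, 0.2 * bo),
    se = c(rep(0.01, 4), rep(0.005, 4))), trait = "exposure")
  outcome <- make_table(tibble::tibble(
    variant_id = c(ids_e, ids_o),
    pos = seq(1e6, by = 1e6, length.out = 8),
    beta = c(0.3 * bx, bo),
    se = c(rep(0.02, 4), rep(0.01, 4))), trait = "outcome")
  ld <- diag(8)
  dimnames(ld) <- list(c(ids_e, ids_o), c(ids_e, ids_o))
  list(exposure = exposure, outcome = outcome, ld = ld)
}

test_that("sign-consistency handles zeros and mixed signs", {
  expect_true(protscreen:::consistent_direction(c(0.1, 0.2, 0.05)))
  expect_true(protscreen:::consistent_direction(c(-0.1, -0.2)))
  expect_false(protscreen:::consistent_direction(c(0.1, -0.2)))
  expect_false(protscreen:::consistent_direction(c(0.1, 0))) # zero conflicts
  expect_false(protscreen:::consistent_direction(numeric(0)))
})

test_that("step i excludes pairs with consistent significant reverse signals", {
  tabs <- bidirectional_tables()
  dec <- screen_step_i(tabs$exposure, tabs$outcome, tabs$ld,
                       screen_config(boot_reps = 50, seed = 1))
  expect_false(dec$identified) # both directions consistent: conflicted
  expect_s3_class(dec$steiger_forward, "steiger_result")
  expect_true(any(grepl("conflict: TRUE", dec$reasons)))
})

test_that("step i identifies a clean forward-only causal pair", {
  st <- simulate_study(sim_config(seed = 61, n_proteins = 1, mediator = 0,
                                  theta_direct = 0.1))
  dec <- screen_step_i(st$tables$exposure, st$tables$outcome, st$ld,
                       screen_config(boot_reps = 100, seed = 2))
  expect_true(dec$identified)
  expect_true(dec$steiger_forward$correct_direction)
  # swapping the roles must not be identified: the forward arm now uses the
  # outcome's own QTLs, which do not move the exposure
  dec_rev <- screen_step_i(st$tables$outcome, st$tables$exposure, st$ld,
                           screen_config(boot_reps = 100, seed = 3))
  expect_false(dec_rev$identified)
})

test_that("conflict set logic mirrors the forward-minus-overlap rule", {
  res <- unconflicted_associations(c("a", "b", "c"), character(0))
  expect_equal(res$unconflicted, c("a", "b", "c"))
  res2 <- unconflicted_associations(c("a", "b"), c("a", "b", "c"))
  expect_equal(res2$n_unconflicted, 0)
  res3 <- unconflicted_associations(c("a", "b", "c"), c("b", "x"))
  expect_equal(res3$overlap, "b")
  expect_setequal(res3$unconflicted, c("a", "c"))
})

test_that("corroboration logic drops weakly colocalizing pairs", {
  pairs <- tibble::tibble(pair = c("p1", "p2", "p3"), h4 = c(0.95, 0.4, 0.85))
  res <- corroborated_associations(pairs)
  expect_setequal(res$identified, c("p1", "p3"))
  expect_equal(res$not_corroborated, "p2")
})

test_that("mediation calls require attenuation plus a CI crossing the null", {
  # identical estimates: nothing attenuated
  same <- mediation_call(0.12, 0.02, 0.22, 0.12, 0.02, 0.22)
  expect_false(same$mediation_flag)
  # adjusted estimate farther from the null
  worse <- mediation_call(0.12, 0.02, 0.22, 0.18, 0.08, 0.28)
  expect_false(worse$mediation_flag)
  # attenuated but still excluding the null
  part <- mediation_call(0.12, 0.02, 0.22, 0.08, 0.01, 0.15)
  expect_true(part$attenuated)
  expect_false(part$mediation_flag)
  # the full signature
  full <- mediation_call(0.12, 0.02, 0.22, 0.06, -0.04, 0.16)
  expect_true(full$mediation_flag)
})

test_that("step ii and iii isolate the planted mediator protein", {
  st <- simulate_study(sim_config(seed = 62, n_proteins = 5))
  prots <- st$tables[sprintf("P%02d", 1:5)]
  eff <- effective_tests(estimate_pheno_corr(prots))
  cfg <- screen_config(boot_reps = 200, seed = 4)
  s2 <- screen_step_ii(st$tables$exposure, prots, st$ld,
                       eff$alpha_corrected, cfg)
  expect_equal(s2$unconflicted, "P01")
  s3 <- screen_step_iii(prots, st$tables$outcome, st$genes, st$ld,
                        eff$alpha_corrected, cfg)
  expect_equal(s3$identified, "P01")
  expect_true(all(s3$decisions$n_cis > 0))
})

test_that("the full screen flags the planted mediator and is deterministic", {
  st <- simulate_study(sim_config(seed = 63))
  cfg <- screen_config(seed = 5)
  res <- run_screen(st, cfg)
  expect_equal(res$flagged_mediators, "P01")
  expect_equal(res$flagged_mediators, st$truth$mediators)
  # decision provenance: the recorded verdict components re-evaluate to the flag
  call <- res$step_iv$P01$call
  expect_equal(call$mediation_flag,
               call$attenuated && call$ci_now_overlaps_null &&
                 call$uvmr_excludes_null)
  res2 <- run_screen(st, cfg)
  expect_identical(glance(res), glance(res2))
  expect_identical(tidy(res), tidy(res2))
  expect_identical(res$trace, res2$trace)
})

test_that("a global-null study produces no identifications", {
  cfg0 <- sim_config(seed = 64, mediator = 0, theta_direct = 0)
  st0 <- simulate_study(cfg0)
  res0 <- run_screen(st0, screen_config(seed = 6))
  expect_length(res0$flagged_mediators, 0)
  expect_length(res0$step_ii$unconflicted, 0)
})

test_that("screen results serialize to result tables and a run log", {
  st <- simulate_study(sim_config(seed = 65, n_proteins = 3))
  res <- run_screen(st, screen_config(seed = 7))
  dir <- withr::local_tempdir()
  write_screen_results(res, dir)
  expect_true(all(file.exists(file.path(dir, c(
    "step_i_models.tsv", "step_ii_decisions.tsv", "step_iii_decisions.tsv",
    "step_iv_calls.tsv", "decisions.tsv", "run.json")))))
  run <- jsonlite::read_json(file.path(dir, "run.json"))
  expect_equal(run$thresholds$alpha_corrected, res$alpha_corrected)
  d2 <- readr::read_tsv(file.path(dir, "step_ii_decisions.tsv"),
                        show_col_types = FALSE)
  expect_equal(nrow(d2), 3)
})
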