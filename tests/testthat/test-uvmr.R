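wald_set <- function(bx, by, se_x = 0.01, se_y = 0.02) {
  tibble::tibble(variant_id = sprintf("v%d", seq_along(bx)),
                 beta_exp = bx, se_exp = se_x, beta_out = by, se_out = se_y,
                 action = "kept")
}

test_that("the Wald ratio follows the delta-method arithmetic", {
  fit <- mr_wald_ratio(wald_set(0.1, 0.05, 0.01, 0.02))
  expect_equal(fit$estimate, 0.5)
  expect_equal(fit$se, 0.2)
  expect_equal(mr_wald_ratio(wald_set(0.1, 0))$estimate, 0)
  expect_error(mr_wald_ratio(wald_set(0, 0.1)),
               class = "protscreen_degenerate_instrument_error")
  # scale equivariance: doubling the exposure effect halves the ratio
  set.seed(4)
  for (i in 1:10) {
    bx <- runif(1, 0.05, 0.2); by <- rnorm(1, 0.1, 0.05)
    expect_equal(mr_wald_ratio(wald_set(2 * bx, by))$estimate,
                 mr_wald_ratio(wald_set(bx, by))$estimate / 2)
  }
})

test_that("IVW-MRE reproduces the closed form and the regression oracle", {
  h <- wald_set(c(1, 1), c(1, 3), se_x = 0.01, se_y = 1)
  fit <- mr_ivw_mre(h)
  expect_equal(fit$estimate, 2)
  expect_equal(fit$Q, 2)
  expect_equal(fit$se, 1)
  # identical per-variant ratios: theta = ratio, Q = 0
  h2 <- wald_set(c(0.1, 0.2, 0.4), c(0.05, 0.1, 0.2))
  fit2 <- mr_ivw_mre(h2)
  expect_equal(fit2$estimate, 0.5)
  expect_equal(fit2$Q, 0, tolerance = 1e-24)
  # brute-force weighted-least-squares oracle
  set.seed(9)
  for (i in 1:20) {
    k <- 30
    h3 <- wald_set(rnorm(k, 0.1, 0.03), rnorm(k, 0.03, 0.02),
                   se_y = runif(k, 0.01, 0.05))
    got <- mr_ivw_mre(h3)
    want <- oracle_ivw(h3$beta_exp, h3$beta_out, h3$se_out)
    expect_equal(got$estimate, want$theta, tolerance = 1e-10)
    expect_equal(got$se, want$se, tolerance = 1e-10)
  }
})

test_that("Egger is orientation-invariant and recovers planted pleiotropy", {
  h <- harmonized_effects(sim_harmonized(k = 50, theta = 0.3, seed = 21))
  base <- mr_egger(h)
  h_flip <- h
  h_flip$beta_exp[3] <- -h$beta_exp[3]
  h_flip$beta_out[3] <- -h$beta_out[3]
  flip <- mr_egger(h_flip)
  expect_equal(flip$estimate, base$estimate)
  expect_equal(flip$egger_intercept, base$egger_intercept)
  # constant pleiotropy +c on every outcome effect shows up as the intercept
  c_off <- 0.04
  h_pl <- h
  h_pl$beta_out <- h_pl$beta_out + c_off * sign(h_pl$beta_exp)
  fit <- mr_egger(h_pl)
  expect_lt(abs(fit$egger_intercept - c_off), 3 * fit$egger_intercept_se)
  expect_error(mr_egger(wald_set(c(0.1, 0.1, 0.1), c(0.05, 0.05, 0.05))),
               class = "protscreen_degenerate_instrument_error")
})

test_that("Egger slope and intercept CIs are calibrated on clean data", {
  cover_slope <- cover_int <- 0
  for (r in 1:100) {
    h <- sim_harmonized(k = 100, theta = 0.3, seed = 500 + r)
    fit <- mr_egger(h)
    tq <- qt(0.975, df = 98)
    cover_slope <- cover_slope +
      (abs(fit$estimate - 0.3) <= tq * fit$se)
    cover_int <- cover_int +
      (abs(fit$egger_intercept) <= tq * fit$egger_intercept_se)
  }
  expect_gte(cover_slope, 90)
  expect_gte(cover_int, 90)
})

test_that("the weighted median matches a brute-force percentile oracle", {
  h <- wald_set(c(1, 1, 1), c(1, 1, 1))
  expect_equal(mr_weighted_median(h, boot_reps = 50, seed = 1)$estimate, 1)
  # ratios {0, 1, 100} with weights {0.1, 0.8, 0.1} -> 1
  expect_equal(oracle_weighted_percentile(c(0, 1, 100), c(0.1, 0.8, 0.1)), 1)
  set.seed(31)
  for (i in 1:10) {
    k <- 15
    h2 <- wald_set(runif(k, 0.05, 0.2), rnorm(k, 0.05, 0.05),
                   se_y = runif(k, 0.01, 0.05))
    got <- mr_weighted_median(h2, boot_reps = 10, seed = i)$estimate
    rs <- protscreen:::ratio_stats(h2)
    expect_equal(got, oracle_weighted_percentile(rs$ratio, rs$w))
  }
  # order invariance
  h3 <- wald_set(c(0.1, 0.2, 0.15, 0.3), c(0.02, 0.08, 0.02, 0.1))
  perm <- h3[c(3, 1, 4, 2), ]
  expect_equal(mr_weighted_median(perm, boot_reps = 10, seed = 2)$estimate,
               mr_weighted_median(h3, boot_reps = 10, seed = 2)$estimate)
})

test_that("the weighted mode finds the dominant ratio cluster", {
  h <- wald_set(rep(0.1, 3), rep(0.07, 3))
  expect_equal(mr_weighted_mode(h, boot_reps = 10, seed = 1)$estimate, 0.7)
  # 70% of weight near 0.5, 30% near 5.0
  set.seed(12)
  k <- 20
  ratio_true <- c(rep(0.5, 14), rep(5, 6))
  bx <- runif(k, 0.09, 0.11)
  h2 <- wald_set(bx, ratio_true * bx + rnorm(k, 0, 0.002), se_y = 0.01)
  est <- mr_weighted_mode(h2, boot_reps = 10, seed = 3)$estimate
  expect_lt(abs(est - 0.5), 0.1)
  perm <- h2[sample(k), ]
  expect_equal(mr_weighted_mode(perm, boot_reps = 10, seed = 4)$estimate, est)
})

test_that("estimators collapse to the Wald ratio on one effective variant", {
  h <- wald_set(rep(0.1, 4), rep(0.05, 4))
  wald <- mr_wald_ratio(h[1, ])
  expect_equal(mr_ivw_mre(h)$estimate, wald$estimate)
  expect_equal(mr_weighted_median(h, boot_reps = 10, seed = 1)$estimate,
               wald$estimate)
  expect_equal(mr_weighted_mode(h, boot_reps = 10, seed = 1)$estimate,
               wald$estimate)
})

test_that("negating the exposure negates every point estimate", {
  h <- harmonized_effects(sim_harmonized(k = 20, theta = 0.25, seed = 77))
  neg <- h
  neg$beta_exp <- -neg$beta_exp
  expect_equal(mr_ivw_mre(neg)$estimate, -mr_ivw_mre(h)$estimate)
  expect_equal(mr_egger(neg)$estimate, -mr_egger(h)$estimate)
  expect_equal(mr_weighted_median(neg, boot_reps = 10, seed = 5)$estimate,
               -mr_weighted_median(h, boot_reps = 10, seed = 5)$estimate)
  expect_equal(mr_weighted_mode(neg, boot_reps = 10, seed = 6)$estimate,
               -mr_weighted_mode(h, boot_reps = 10, seed = 6)$estimate)
  expect_equal(mr_wald_ratio(neg[1, ])$estimate,
               -mr_wald_ratio(h[1, ])$estimate)
})

test_that("leave-one-out isolates a planted outlier", {
  h <- harmonized_effects(sim_harmonized(k = 12, theta = 0.2, seed = 41))
  loo <- mr_leave_one_out(h)
  expect_equal(nrow(loo), 12)
  full <- mr_ivw_mre(h)$estimate
  expect_true(all(abs(loo$estimate - full) < 0.1))
  # plant one dominant outlier
  h$beta_out[5] <- h$beta_out[5] + 1
  loo2 <- mr_leave_one_out(h)
  shifts <- abs(loo2$estimate - mr_ivw_mre(h)$estimate)
  expect_equal(loo2$omitted[which.max(shifts)], h$variant_id[5])
})

test_that("Steiger directionality reads the explained-variance comparison", {
  h <- wald_set(c(0.2, 0.2, 0.2), c(0.01, 0.012, 0.008),
                se_x = 0.01, se_y = 0.01)
  res <- mr_steiger(h, n_exp = 20000, n_out = 20000)
  expect_true(res$correct_direction)
  expect_true(res$r2_exposure > res$r2_outcome)
  # symmetric effects: z = 0, p = 1
  h_eq <- wald_set(0.2, 0.2, se_x = 0.01, se_y = 0.01)
  res_eq <- mr_steiger(h_eq, n_exp = 20000, n_out = 20000)
  expect_equal(res_eq$z, 0)
  expect_equal(res_eq$pval, 1)
  expect_error(mr_steiger(h, n_exp = 2, n_out = 20000),
               class = "protscreen_domain_error")
})

test_that("Steiger calls the simulated causal direction at n = 20,000", {
  correct <- 0
  for (r in 1:100) {
    h <- sim_harmonized(k = 15, theta = 0.3, se_exp = 1 / sqrt(20000),
                        se_out = 1 / sqrt(20000), seed = 900 + r)
    res <- mr_steiger(h, n_exp = 20000, n_out = 20000)
    correct <- correct + res$correct_direction
  }
  expect_gte(correct, 95)
})

test_that("model dispatch runs every applicable estimator", {
  h1 <- wald_set(0.1, 0.05)
  expect_equal(mr_all_models(h1)$method, "wald")
  h2 <- wald_set(c(0.1, 0.2), c(0.05, 0.1))
  expect_equal(mr_all_models(h2)$method, "ivw_mre")
  h5 <- harmonized_effects(sim_harmonized(k = 5, seed = 3))
  tbl <- mr_all_models(h5, boot_reps = 20, seed = 1)
  expect_equal(tbl$method,
               c("ivw_mre", "egger", "weighted_median", "weighted_mode"))
  expect_true(all(tbl$ci_low <= tbl$estimate & tbl$estimate <= tbl$ci_high))
})
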