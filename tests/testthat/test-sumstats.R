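test_that("a well-formed file round-trips field for field", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  st <- simulate_study(sim_config(seed = 3, n_proteins = 2,
                                  n_exposure_qtl_regions = 2,
                                  n_outcome_qtl_regions = 1))
  tab <- st$tables$exposure
  write_sumstats(tab, tf)
  back <- read_sumstats(tf, trait_id = "exposure")
  expect_equal(nrow(back), nrow(tab))
  expect_equal(back$variant_id, tab$variant_id)
  for (col in c("pos", "eaf", "beta", "se", "pval", "n")) {
    expect_equal(back[[col]], tab[[col]], tolerance = 1e-12)
  }
})

test_that("a three-row file yields three records and bad rows are named", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  hdr <- paste(c("variant_id", "chrom", "pos", "effect_allele", "other_allele",
                 "eaf", "beta", "se", "pval", "n", "n_case", "n_control"),
               collapse = "\t")
  rows <- c("v1\tchr1\t100\tA\tG\t0.2\t0.1\t0.05\t0.04\t1000\tNA\tNA",
            "v2\tchr1\t200\tC\tT\t0.3\t0.2\t0.02\t0.001\t1000\tNA\tNA",
            "v3\tchr1\t300\tG\tA\t0.4\t-0.1\t0.03\t0.2\t1000\tNA\tNA")
  writeLines(c(hdr, rows), tf)
  expect_equal(nrow(read_sumstats(tf)), 3L)

  rows[2] <- "v2\tchr1\t200\tC\tT\t0.3\t0.2\t0\t0.001\t1000\tNA\tNA"
  writeLines(c(hdr, rows), tf)
  err <- expect_error(read_sumstats(tf), class = "protscreen_validation_error")
  expect_match(conditionMessage(err), "row 2")

  writeLines(c(sub("\tse", "\tstderr", hdr), rows), tf)
  expect_error(suppressWarnings(read_sumstats(tf)),
               class = "protscreen_format_error")
})

test_that("harmonization keeps, flips, and drops as the allele coding demands", {
  e <- make_table(tibble::tibble(variant_id = c("v1", "v2", "v3"),
                                 effect_allele = c("A", "A", "A"),
                                 other_allele = c("C", "C", "T"),
                                 eaf = c(0.3, 0.3, 0.5),
                                 beta = c(0.1, 0.1, 0.1), se = 0.01),
                  trait = "exp")
  o <- make_table(tibble::tibble(variant_id = c("v1", "v2", "v3"),
                                 effect_allele = c("A", "C", "T"),
                                 other_allele = c("C", "A", "A"),
                                 eaf = c(0.3, 0.7, 0.5),
                                 beta = c(0.05, 0.2, 0.3), se = 0.02),
                  trait = "out")
  h <- harmonize(e, o)
  expect_equal(h$action, c("kept", "flipped", "dropped_palindromic"))
  expect_equal(h$beta_out[1], 0.05)
  expect_equal(h$beta_out[2], -0.2) # swapped alleles: sign flip
  expect_true(is.na(h$beta_out[3])) # A/T at eaf 0.5: unresolvable
})

test_that("harmonization is involutive under full outcome recoding", {
  st <- simulate_study(sim_config(seed = 11, n_proteins = 2,
                                  n_exposure_qtl_regions = 3,
                                  n_outcome_qtl_regions = 1))
  e <- st$tables$exposure
  o <- st$tables$outcome
  o_flipped <- o
  o_flipped$effect_allele <- o$other_allele
  o_flipped$other_allele <- o$effect_allele
  o_flipped$beta <- -o$beta
  o_flipped$eaf <- 1 - o$eaf
  attr(o_flipped, "trait_id") <- "outcome"
  attr(o_flipped, "trait_type") <- "case_control"
  h1 <- harmonize(e, o)
  h2 <- harmonize(e, o_flipped)
  expect_equal(h1$beta_out, h2$beta_out)
  expect_equal(h1$se_out, h2$se_out)
  keep <- select_genome_wide(e, st$ld)
  fit1 <- mr_ivw_mre(harmonize(keep, o))
  fit2 <- mr_ivw_mre(harmonize(keep, o_flipped))
  expect_equal(fit1$estimate, fit2$estimate)
  expect_equal(fit1$se, fit2$se)
})

test_that("clumping matches a brute-force greedy oracle and is idempotent", {
  set.seed(7)
  n <- 50
  ids <- sprintf("v%02d", 1:n)
  ld <- protscreen:::ar1_matrix(n, 0.95, ids)
  tab <- make_table(tibble::tibble(
    variant_id = ids, pos = seq(1e6, by = 5e3, length.out = n),
    beta = rnorm(n, 0, 0.05), se = 0.01,
    pval = runif(n, 1e-12, 1)
  ))
  got <- ld_clump(tab, ld, r2_threshold = 0.01, window_kb = 10000)
  want <- oracle_clump_ids(tab, ld, 0.01, 10000)
  expect_setequal(got$variant_id, want)
  # survivors pairwise independent within the window
  for (i in seq_len(nrow(got))) {
    for (j in seq_len(nrow(got))) {
      if (i == j) next
      close_by <- abs(got$pos[i] - got$pos[j]) <= 1e7
      if (close_by) {
        expect_lte(ld[got$variant_id[i], got$variant_id[j]]^2, 0.01)
      }
    }
  }
  again <- ld_clump(got, ld, r2_threshold = 0.01, window_kb = 10000)
  expect_equal(again$variant_id, got$variant_id)
})

test_that("clumping keeps singletons, picks the smaller p, and drops unassessable variants", {
  ids <- c("a", "b")
  ld <- matrix(c(1, sqrt(0.5), sqrt(0.5), 1), 2, dimnames = list(ids, ids))
  tab <- make_table(tibble::tibble(variant_id = ids, pos = c(1e6, 1.1e6),
                                   beta = c(0.1, 0.1), se = 0.01,
                                   pval = c(1e-10, 1e-9)))
  out <- ld_clump(tab, ld, r2_threshold = 0.001, window_kb = 10000)
  expect_equal(out$variant_id, "a")
  expect_equal(ld_clump(tab[1, ], ld)$variant_id, "a")
  tab2 <- make_table(tibble::tibble(variant_id = c("a", "zz"),
                                    pos = c(1e6, 2e6), beta = 0.1, se = 0.01,
                                    pval = c(1e-10, 1e-9)))
  expect_warning(out2 <- ld_clump(tab2, ld), "absent from the LD matrix")
  expect_equal(out2$variant_id, "a")
})

test_that("proxy lookup honours the r-squared threshold and argmax rule", {
  ids <- c("t", "p1", "p2")
  r <- diag(3); dimnames(r) <- list(ids, ids)
  r["t", "p1"] <- r["p1", "t"] <- -sqrt(0.7)
  r["t", "p2"] <- r["p2", "t"] <- sqrt(0.9)
  out <- make_table(tibble::tibble(variant_id = c("p1", "p2"),
                                   beta = c(0.1, 0.2), se = 0.02))
  hit <- find_proxy("t", out, r, min_r2 = 0.64)
  expect_equal(hit$proxy, "p2")
  expect_equal(hit$r2, 0.9)
  out_t <- make_table(tibble::tibble(variant_id = "t", beta = 0.1, se = 0.02))
  self <- find_proxy("t", out_t, r)
  expect_equal(self$proxy, "t")
  expect_equal(self$r2, 1)
  weak <- diag(3); dimnames(weak) <- list(ids, ids)
  weak["t", "p1"] <- weak["p1", "t"] <- sqrt(0.5)
  expect_equal(nrow(find_proxy("t", out, weak, min_r2 = 0.64)), 0L)
  expect_error(find_proxy("missing", out, r),
               class = "protscreen_lookup_error")
})

test_that("proxy substitution orients the outcome effect by the sign of r", {
  ids <- c("t", "p")
  r <- matrix(c(1, -0.95, -0.95, 1), 2, dimnames = list(ids, ids))
  e <- make_table(tibble::tibble(variant_id = "t", beta = 0.1, se = 0.01),
                  trait = "exp")
  o <- make_table(tibble::tibble(variant_id = "p", beta = 0.2, se = 0.02),
                  trait = "out")
  h <- harmonize(e, o, proxies = TRUE, ld = r, min_r2 = 0.8)
  expect_equal(h$action, "proxied")
  expect_equal(h$beta_out, -0.2)
})

test_that("LD matrices round-trip through the on-disk dialect", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  ids <- sprintf("v%d", 1:4)
  r <- protscreen:::ar1_matrix(4, 0.8, ids)
  write_ld_matrix(r, tf)
  back <- read_ld_matrix(tf)
  expect_equal(back, r, tolerance = 1e-12)
  bad <- r; bad[1, 2] <- 0.5
  write_ld_matrix(bad, tf)
  expect_error(read_ld_matrix(tf), class = "protscreen_validation_error")
})
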