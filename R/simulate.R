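#' Configuration for the synthetic mediation study
#'
#' Defines the default synthetic study the package validates itself on: one
#' continuous adiposity-like exposure, a panel of continuous circulating
#' proteins (one of which truly mediates), and one case-control
#' colorectal-cancer-like outcome, all as two-sample GWAS summary statistics
#' over an AR-1 LD panel. Traits are on the inverse-rank-normal
#' (unit-variance) scale; the outcome is on the log-odds scale.
#'
#' The genetic architecture: the exposure has `n_exposure_qtl_regions`
#' independent QTL regions (one causal variant each, variance explained drawn
#' from `exposure_qtl_var`); each protein has `cis_qtls_per_protein` causal
#' variants in its own 1-region cis window plus one trans QTL in a shared
#' trans region; the outcome has its own QTL regions (so reverse MR is
#' testable). Causal structure: exposure -> protein effects
#' `alpha_exp_protein` (SD units), protein -> outcome effects
#' `gamma_protein_outcome` (log-odds per SD), and a direct exposure ->
#' outcome effect `theta_direct`. By default only `mediator` carries the
#' mediated path.
#'
#' @param seed Integer seed; all randomness derives from it.
#' @param n_proteins Number of protein traits.
#' @param mediator Index of the planted mediator protein (0 for none).
#' @param region_size Variants per LD region.
#' @param spacing_bp Base pairs between adjacent variants.
#' @param rho AR-1 LD correlation between adjacent variants.
#' @param maf_range Uniform bounds for minor-allele frequencies.
#' @param n_exposure,n_protein Cohort sizes for the continuous traits.
#' @param n_case,n_control Outcome case/control counts.
#' @param n_exposure_qtl_regions,exposure_qtl_var Exposure architecture.
#' @param n_outcome_qtl_regions,outcome_qtl_beta Outcome-specific QTLs
#'   (standardized log-odds per QTL).
#' @param n_trans_regions Shared trans-pQTL regions.
#' @param cis_qtls_per_protein,cis_qtl_var,trans_qtl_var Protein architecture
#'   (variance-explained ranges / values).
#' @param alpha_exp_protein Exposure -> protein effects (length
#'   `n_proteins`); default 0 except `mediator` at 0.2 SD.
#' @param gamma_protein_outcome Protein -> outcome effects; default 0 except
#'   `mediator` at 0.3 log-odds per SD.
#' @param theta_direct Direct exposure -> outcome effect (log-odds per SD).
#' @param pleiotropy_frac,pleiotropy_mean,pleiotropy_sd Optional direct
#'   variant -> outcome paths planted at this fraction of exposure QTLs.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_proteins = 50L,
                       mediator = 1L,
                       region_size = 50L,
                       spacing_bp = 10000L,
                       rho = 0.9,
                       maf_range = c(0.05, 0.5),
                       n_exposure = 1e5,
                       n_protein = 35000,
                       n_case = 25000,
                       n_control = 25000,
                       n_exposure_qtl_regions = 30L,
                       exposure_qtl_var = c(0.002, 0.012),
                       n_outcome_qtl_regions = 5L,
                       outcome_qtl_beta = 0.04,
                       n_trans_regions = 2L,
                       cis_qtls_per_protein = 3L,
                       cis_qtl_var = c(0.01, 0.02),
                       trans_qtl_var = 0.01,
                       alpha_exp_protein = NULL,
                       gamma_protein_outcome = NULL,
                       theta_direct = 0.005,
                       pleiotropy_frac = 0,
                       pleiotropy_mean = 0,
                       pleiotropy_sd = 0) {
  if (is.null(alpha_exp_protein)) {
    alpha_exp_protein <- rep(0, n_proteins)
    if (mediator > 0) alpha_exp_protein[mediator] <- 0.2
  }
  if (is.null(gamma_protein_outcome)) {
    gamma_protein_outcome <- rep(0, n_proteins)
    if (mediator > 0) gamma_protein_outcome[mediator] <- 0.3
  }
  stopifnot(length(alpha_exp_protein) == n_proteins,
            length(gamma_protein_outcome) == n_proteins,
            rho >= 0, rho < 1,
            n_exposure > 0, n_protein > 0, n_case > 0, n_control > 0)
  structure(as.list(environment()), class = "sim_config")
}

ar1_matrix <- function(n, rho, ids = NULL) {
  r <- rho^abs(outer(seq_len(n), seq_len(n), "-"))
  if (!is.null(ids)) dimnames(r) <- list(ids, ids)
  r
}

#' Simulate the LD panel
#'
#' Builds the variant map (region, chromosome, position, allele pair, allele
#' frequency) and one AR-1 correlation block per region,
#' `r_ij = rho^|i - j|`. Regions sit on distinct chromosomes, so the full
#' panel is block diagonal (returned as an [ld_blocks()] object).
#'
#' @param config A [sim_config()].
#' @return List with `variants` (tibble), `ld` (`ld_blocks`), and `genes`
#'   (per-protein transcription start site annotation).
#' @export
simulate_panel <- function(config) {
  cf <- config
  region_names <- c(
    sprintf("E%02d", seq_len(cf$n_exposure_qtl_regions)),
    sprintf("C%02d", seq_len(cf$n_proteins)),
    sprintf("T%02d", seq_len(cf$n_trans_regions)),
    sprintf("O%02d", seq_len(cf$n_outcome_qtl_regions))
  )
  alleles <- c("A", "C", "G", "T")
  variants <- withr_seed(cf$seed, {
    list_rbind(map(region_names, function(rg) {
      ea <- sample(alleles, cf$region_size, replace = TRUE)
      oa <- vapply(ea, function(a) sample(setdiff(alleles, c(a, comp_allele(a))), 1),
                   character(1)) # avoid palindromic pairs in the panel
      tibble(
        variant_id = sprintf("%s_%02d", rg, seq_len(cf$region_size)),
        region = rg,
        chrom = paste0("chr", rg),
        pos = 1000000L + (seq_len(cf$region_size) - 1L) * cf$spacing_bp,
        effect_allele = ea, other_allele = unname(oa),
        eaf = runif(cf$region_size, cf$maf_range[1], cf$maf_range[2])
      )
    }))
  })
  blocks <- lapply(setNames(region_names, region_names), function(rg) {
    ids <- variants$variant_id[variants$region == rg]
    ar1_matrix(cf$region_size, cf$rho, ids)
  })
  genes <- tibble(
    gene_id = sprintf("P%02d", seq_len(cf$n_proteins)),
    chrom = paste0("chrC", sprintf("%02d", seq_len(cf$n_proteins))),
    tss = 1000000L + (cf$region_size %/% 2L) * cf$spacing_bp
  )
  list(variants = variants, ld = ld_blocks(blocks), genes = genes)
}

#' Simulate a linked two-sample GWAS study with known causal structure
#'
#' Generates per-trait summary statistics at the summary level: expected
#' standardized marginal effects are the true joint (causal) effects
#' propagated through the region's LD (`mu = R b`), and observed z-scores are
#' `sqrt(n_eff) * mu` plus LD-correlated noise drawn independently per trait
#' (two-sample designs share no noise). Per-allele effects and standard
#' errors follow `se = 1/sqrt(2 f (1 - f) n_eff)`; for the case-control
#' outcome `n_eff = 4 / (1/n_case + 1/n_control)` on the log-odds scale.
#'
#' @param config A [sim_config()].
#' @return A list with `tables` (named list of summary-statistic tibbles:
#'   `exposure`, `P01`...`Pnn`, `outcome`), `ld`, `genes`, and `truth`
#'   (joint-effect matrix, causal coefficients, planted mediator ids,
#'   per-region causal variants).
#' @export
simulate_study <- function(config) {
  cf <- config
  panel <- simulate_panel(cf)
  v <- panel$variants
  nv <- nrow(v)
  protein_ids <- sprintf("P%02d", seq_len(cf$n_proteins))
  traits <- c("exposure", protein_ids, "outcome")
  nt <- length(traits)

  withr_seed(cf$seed + 1L, {
    # joint (causal) standardized effects, one column per trait
    B <- matrix(0, nv, nt, dimnames = list(v$variant_id, traits))
    causal <- list()

    # exposure QTLs: one causal variant per E region
    e_regions <- sprintf("E%02d", seq_len(cf$n_exposure_qtl_regions))
    for (rg in e_regions) {
      idx <- which(v$region == rg)
      pick <- sample(idx, 1)
      ve <- runif(1, cf$exposure_qtl_var[1], cf$exposure_qtl_var[2])
      B[pick, "exposure"] <- sample(c(-1, 1), 1) * sqrt(ve)
      causal[[rg]] <- v$variant_id[pick]
    }
    b_exp <- B[, "exposure"]

    # protein QTLs: cis in own region + one trans QTL in a shared region
    for (k in seq_len(cf$n_proteins)) {
      rg <- sprintf("C%02d", k)
      idx <- which(v$region == rg)
      # well-separated cis causal variants; the first (central) one dominates,
      # as is typical of cis-pQTL regions with one lead signal plus minor
      # secondaries
      fr <- c(0.5, 0.2, 0.8, 0.35, 0.65)
      fr <- fr[seq_len(min(cf$cis_qtls_per_protein, length(fr)))]
      pick <- idx[round(fr * (cf$region_size - 1)) + 1]
      vc <- runif(length(pick), cf$cis_qtl_var[1], cf$cis_qtl_var[2])
      if (length(vc) > 1) vc[-1] <- vc[-1] / 5
      B[pick, protein_ids[k]] <- sample(c(-1, 1), length(pick), TRUE) * sqrt(vc)
      causal[[rg]] <- v$variant_id[pick]
      trans_rg <- sprintf("T%02d", ((k - 1) %% cf$n_trans_regions) + 1)
      tidx <- which(v$region == trans_rg)
      slot <- ((k - 1) %/% cf$n_trans_regions) * 2 + 1
      slot <- min(slot, length(tidx))
      B[tidx[slot], protein_ids[k]] <- sample(c(-1, 1), 1) * sqrt(cf$trans_qtl_var)
      # mediated component: exposure QTLs shift the protein
      B[, protein_ids[k]] <- B[, protein_ids[k]] +
        cf$alpha_exp_protein[k] * b_exp
    }

    # outcome: own QTLs + direct path + mediated paths (+ pleiotropy)
    o_regions <- sprintf("O%02d", seq_len(cf$n_outcome_qtl_regions))
    for (rg in o_regions) {
      idx <- which(v$region == rg)
      pick <- sample(idx, 1)
      B[pick, "outcome"] <- sample(c(-1, 1), 1) * cf$outcome_qtl_beta
      causal[[rg]] <- v$variant_id[pick]
    }
    B[, "outcome"] <- B[, "outcome"] + cf$theta_direct * b_exp
    for (k in seq_len(cf$n_proteins)) {
      B[, "outcome"] <- B[, "outcome"] +
        cf$gamma_protein_outcome[k] * B[, protein_ids[k]]
    }
    if (cf$pleiotropy_frac > 0) {
      eqtl <- which(b_exp != 0)
      n_pl <- ceiling(cf$pleiotropy_frac * length(eqtl))
      hit <- sample(eqtl, n_pl)
      B[hit, "outcome"] <- B[hit, "outcome"] +
        rnorm(n_pl, cf$pleiotropy_mean, cf$pleiotropy_sd)
    }

    n_out <- cf$n_case + cf$n_control
    n_eff <- c(cf$n_exposure, rep(cf$n_protein, cf$n_proteins),
               4 / (1 / cf$n_case + 1 / cf$n_control))
    names(n_eff) <- traits

    # marginal z-scores: sqrt(n_eff) * R b + LD-correlated noise per trait
    Z <- matrix(0, nv, nt, dimnames = list(v$variant_id, traits))
    for (rg in unique(v$region)) {
      idx <- which(v$region == rg)
      R <- panel$ld$blocks[[rg]]
      mu <- R %*% B[idx, , drop = FALSE]
      Lt <- t(chol(R + diag(1e-10, length(idx))))
      eps <- Lt %*% matrix(rnorm(length(idx) * nt), length(idx), nt)
      Z[idx, ] <- sweep(mu, 2, sqrt(n_eff), "*") + eps
    }

    scale_allele <- 1 / sqrt(2 * v$eaf * (1 - v$eaf))
    tables <- imap(setNames(traits, traits), function(tr, nm) {
      ne <- n_eff[[tr]]
      se <- scale_allele / sqrt(ne)
      z <- unname(Z[, tr])
      beta <- z * se
      is_out <- tr == "outcome"
      sumstats(
        tibble(
          variant_id = v$variant_id, chrom = v$chrom, pos = v$pos,
          effect_allele = v$effect_allele, other_allele = v$other_allele,
          eaf = v$eaf, beta = beta, se = se,
          pval = pmax(two_sided_p(z), 1e-320),
          n = if (is_out) n_out else ne,
          n_case = if (is_out) cf$n_case else NA_real_,
          n_control = if (is_out) cf$n_control else NA_real_
        ),
        trait_id = tr,
        trait_type = if (is_out) "case_control" else "continuous"
      )
    })

    truth <- list(
      B = B, causal = causal,
      alpha_exp_protein = setNames(cf$alpha_exp_protein, protein_ids),
      gamma_protein_outcome = setNames(cf$gamma_protein_outcome, protein_ids),
      theta_direct = cf$theta_direct,
      mediators = protein_ids[cf$alpha_exp_protein != 0 &
                                cf$gamma_protein_outcome != 0],
      config = cf
    )
    list(tables = tables, ld = panel$ld, genes = panel$genes, truth = truth)
  })
}

#' Simulate a colocalization scenario for one region pair
#'
#' Generates two traits over a single AR-1 region with a known sharing
#' configuration: `shared` (one causal variant drives both traits),
#' `distinct` (two different causal variants, separated by `gap` panel
#' positions), or `null` (no association in either trait).
#'
#' @param mode `"shared"`, `"distinct"` or `"null"`.
#' @param n_variants Variants in the region.
#' @param rho AR-1 LD correlation.
#' @param z_causal Expected z-score at the causal variant(s).
#' @param n1,n2 Per-trait sample sizes.
#' @param gap Index separation of the two causal variants (`distinct` mode).
#' @param spacing_bp Base pairs between adjacent variants.
#' @param seed Integer seed.
#' @return List with `trait1`, `trait2` (summary-statistic tibbles), `ld`
#'   (dense matrix) and `truth` (causal variant ids).
#' @export
simulate_coloc_scenario <- function(mode = c("shared", "distinct", "null"),
                                    n_variants = 200L, rho = 0.95,
                                    z_causal = 8, n1 = 35000, n2 = 50000,
                                    gap = 40L, spacing_bp = 10000L,
                                    seed = 1L) {
  mode <- match.arg(mode)
  ids <- sprintf("V%03d", seq_len(n_variants))
  R <- ar1_matrix(n_variants, rho, ids)
  withr_seed(seed, {
    eaf <- runif(n_variants, 0.05, 0.5)
    mid <- n_variants %/% 2L
    b1 <- b2 <- numeric(n_variants)
    causal1 <- causal2 <- character(0)
    if (mode == "shared") {
      b1[mid] <- z_causal / sqrt(n1)
      b2[mid] <- z_causal / sqrt(n2)
      causal1 <- causal2 <- ids[mid]
    } else if (mode == "distinct") {
      i2 <- min(mid + gap, n_variants)
      b1[mid] <- z_causal / sqrt(n1)
      b2[i2] <- z_causal / sqrt(n2)
      causal1 <- ids[mid]; causal2 <- ids[i2]
    }
    Lt <- t(chol(R + diag(1e-10, n_variants)))
    mk <- function(b, n, tr) {
      z <- sqrt(n) * as.numeric(R %*% b) + as.numeric(Lt %*% rnorm(n_variants))
      se <- 1 / sqrt(2 * eaf * (1 - eaf) * n)
      sumstats(
        tibble(variant_id = ids, chrom = "chr1",
               pos = 1000000L + (seq_len(n_variants) - 1L) * spacing_bp,
               effect_allele = "A", other_allele = "C", eaf = eaf,
               beta = z * se, se = se, pval = pmax(two_sided_p(z), 1e-320),
               n = n, n_case = NA_real_, n_control = NA_real_),
        trait_id = tr
      )
    }
    list(trait1 = mk(b1, n1, "trait1"), trait2 = mk(b2, n2, "trait2"),
         ld = R, truth = list(mode = mode, causal1 = causal1, causal2 = causal2))
  })
}

#' Simulate a harmonized instrument set directly
#'
#' A lightweight generator for estimator-level tests: draws per-variant true
#' exposure effects, applies a causal slope `theta` and optional directional
#' pleiotropy to the outcome effects, and adds independent sampling noise at
#' the stated standard errors. Returns a ready-made harmonized tibble.
#'
#' @param k Number of variants.
#' @param theta True causal effect.
#' @param se_exp,se_out Sampling standard errors (recycled to length `k`).
#' @param beta_exp_range True exposure-effect magnitudes (uniform bounds).
#' @param pleiotropy_frac Fraction of variants with a direct outcome path.
#' @param pleiotropy_mean,pleiotropy_sd Distribution of those direct paths.
#' @param seed Integer seed.
#' @return A harmonized tibble with a `true_pleiotropy` column.
#' @export
sim_harmonized <- function(k = 30L, theta = 0.3, se_exp = 0.01,
                           se_out = 0.05, beta_exp_range = c(0.05, 0.15),
                           pleiotropy_frac = 0, pleiotropy_mean = 0,
                           pleiotropy_sd = 0, seed = NULL) {
  withr_seed(seed, {
    bx_true <- runif(k, beta_exp_range[1], beta_exp_range[2]) *
      sample(c(-1, 1), k, replace = TRUE)
    pl <- numeric(k)
    if (pleiotropy_frac > 0) {
      hit <- sample(k, ceiling(pleiotropy_frac * k))
      # aligned with the exposure-effect sign so a positive mean acts as
      # directional pleiotropy on the ratio scale
      pl[hit] <- rnorm(length(hit), pleiotropy_mean, pleiotropy_sd) *
        sign(bx_true[hit])
    }
    se_exp <- rep_len(se_exp, k); se_out <- rep_len(se_out, k)
    tibble(
      variant_id = sprintf("V%03d", seq_len(k)),
      beta_exp = rnorm(k, bx_true, se_exp), se_exp = se_exp,
      beta_out = rnorm(k, theta * bx_true + pl, se_out), se_out = se_out,
      action = "kept", true_pleiotropy = pl
    )
  })
}

#' Rank-based inverse-normal transform
#'
#' Maps values to normal quantiles by rank using the Blom offset
#' `c = 3/8`: `qnorm((rank - c) / (n - 2c + 1))`. Ties share their average
#' rank. This is the normalization conventionally applied to continuous GWAS
#' traits before analysis, which puts effect sizes on the per-SD scale the
#' simulator and estimators assume.
#'
#' @param values Numeric vector with at least two distinct values.
#' @return The transformed vector (mean approximately 0, variance
#'   approximately 1).
#' @export
int_transform <- function(values) {
  if (length(unique(values[!is.na(values)])) < 2) {
    abort("int_transform requires at least two distinct values",
          class = "protscreen_domain_error")
  }
  c_off <- 3 / 8
  r <- rank(values, ties.method = "average", na.last = "keep")
  n <- sum(!is.na(values))
  qnorm((r - c_off) / (n - 2 * c_off + 1))
}
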