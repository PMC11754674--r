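#' Phenotypic correlation matrix from summary statistics
#'
#' Approximates the pairwise phenotypic correlation between traits as the
#' Pearson correlation of their per-variant z-scores over shared variants,
#' restricted to near-null variants (`|z| < z_cap` in both traits) so that
#' genuine associations do not dominate the estimate.
#'
#' @param tables Named list of summary-statistic tibbles (>= 2 traits).
#' @param z_cap Null-variant cap on |z| (default 1.96).
#' @param min_shared Minimum shared null variants required per pair.
#' @return A symmetric correlation matrix with unit diagonal, dimnames taken
#'   from the list names.
#' @export
estimate_pheno_corr <- function(tables, z_cap = 1.96, min_shared = 100) {
  m <- length(tables)
  if (m < 2) abort("need at least two traits")
  ids <- Reduce(intersect, lapply(tables, function(t) t$variant_id))
  if (length(ids) < min_shared) {
    abort(sprintf("only %d shared variants across all traits (need >= %d)",
                  length(ids), min_shared))
  }
  Z <- vapply(tables, function(t) {
    idx <- match(ids, t$variant_id)
    t$beta[idx] / t$se[idx]
  }, double(length(ids)))
  nullish <- abs(Z) < z_cap
  nm <- names(tables) %||% paste0("trait", seq_len(m))
  r <- diag(1, m)
  dimnames(r) <- list(nm, nm)
  for (i in seq_len(m - 1)) {
    for (j in (i + 1):m) {
      use <- nullish[, i] & nullish[, j]
      if (sum(use) < min_shared) {
        abort(sprintf("insufficient shared null variants for pair %s/%s",
                      nm[i], nm[j]))
      }
      r[i, j] <- r[j, i] <- cor(Z[use, i], Z[use, j])
    }
  }
  r
}

#' Effective number of independent tests from a correlation matrix
#'
#' Spectral-decomposition estimates of the effective number of independent
#' variables among m correlated phenotypes, used to set a multiple-testing
#' threshold less conservative than Bonferroni over m:
#' * Nyholt: `meff = 1 + (m - 1) * (1 - var(lambda)/m)`
#' * Li-Ji: `meff = sum(I(lambda >= 1) + (lambda - floor(lambda)))`
#'
#' where lambda are the eigenvalues of the correlation matrix. The more
#' conservative (larger) of the two is used for the corrected threshold
#' `alpha_corrected = 0.05 / meff_used`.
#'
#' @param corr Square symmetric correlation matrix with unit diagonal.
#' @param alpha Family-wise alpha (default 0.05).
#' @return An object of class `eff_tests` with fields `m`, `meff_nyholt`,
#'   `meff_liji`, `meff_used`, `alpha_corrected`.
#' @export
effective_tests <- function(corr, alpha = 0.05) {
  if (!is.matrix(corr) || nrow(corr) != ncol(corr) ||
      max(abs(corr - t(corr))) > 1e-8 || max(abs(diag(corr) - 1)) > 1e-8) {
    abort("corr must be a square symmetric matrix with unit diagonal",
          class = "protscreen_validation_error")
  }
  m <- nrow(corr)
  lambda <- eigen(corr, symmetric = TRUE, only.values = TRUE)$values
  lambda <- pmax(lambda, 0) # guard tiny negative eigenvalues
  meff_nyholt <- 1 + (m - 1) * (1 - var(lambda) / m)
  meff_liji <- sum(as.numeric(lambda >= 1) + (lambda - floor(lambda)))
  meff_used <- max(meff_nyholt, meff_liji)
  structure(
    list(m = m, meff_nyholt = meff_nyholt, meff_liji = meff_liji,
         meff_used = meff_used, alpha_corrected = alpha / meff_used,
         eigenvalues = lambda),
    class = "eff_tests"
  )
}

#' @export
print.eff_tests <- function(x, ...) {
  cat(sprintf(
    "<eff_tests> m = %d, meff (Nyholt) = %.2f, meff (Li-Ji) = %.2f\n",
    x$m, x$meff_nyholt, x$meff_liji))
  cat(sprintf("  using meff = %.2f -> corrected alpha = %.3g\n",
              x$meff_used, x$alpha_corrected))
  invisible(x)
}
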