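# Independent brute-force oracles, written deliberately differently from the
# package implementations they check.

# greedy p-value clumping, quadratic scan over the dense LD matrix
oracle_clump_ids <- function(tab, ld_mat, r2_thr, window_kb) {
  tab <- tab[order(tab$pval), ]
  kept <- character(0)
  removed <- character(0)
  for (i in seq_len(nrow(tab))) {
    v <- tab$variant_id[i]
    if (v %in% removed) next
    kept <- c(kept, v)
    for (j in seq_len(nrow(tab))) {
      u <- tab$variant_id[j]
      if (u == v || u %in% removed || u %in% kept) next
      close_by <- tab$chrom[j] == tab$chrom[i] &&
        abs(tab$pos[j] - tab$pos[i]) <= window_kb * 1000
      if (close_by && ld_mat[v, u]^2 > r2_thr) removed <- c(removed, u)
    }
  }
  kept
}

# weighted regression through the origin via lm()
oracle_ivw <- function(bx, by, se_y) {
  fit <- lm(by ~ 0 + bx, weights = 1 / se_y^2)
  theta <- unname(coef(fit)[1])
  k <- length(bx)
  q <- sum((by - theta * bx)^2 / se_y^2)
  se <- sqrt((q / (k - 1)) / sum(bx^2 / se_y^2))
  list(theta = theta, se = se, q = q)
}

# weighted 50th percentile by direct scan with linear interpolation
oracle_weighted_percentile <- function(x, w, p = 0.5) {
  o <- order(x)
  x <- x[o]; w <- w[o] / sum(w)
  cw <- cumsum(w) - w / 2
  if (cw[1] >= p) return(x[1])
  if (cw[length(cw)] <= p) return(x[length(x)])
  i <- max(which(cw <= p))
  if (cw[i] == p) return(x[i])
  x[i] + (x[i + 1] - x[i]) * (p - cw[i]) / (cw[i + 1] - cw[i])
}

# log Bayes factor by numerical integration of the two marginal likelihoods
oracle_labf_quadrature <- function(beta, se, prior_sd) {
  m1 <- integrate(function(b) dnorm(beta, b, se) * dnorm(b, 0, prior_sd),
                  lower = -Inf, upper = Inf, rel.tol = 1e-12)$value
  m0 <- dnorm(beta, 0, se)
  log(m1) - log(m0)
}

# effective number of tests from an svd-based spectrum
oracle_meff <- function(corr) {
  lam <- svd(corr)$d # corr is symmetric PSD: singular values = eigenvalues
  m <- nrow(corr)
  nyholt <- 1 + (m - 1) * (1 - var(lam) / m)
  liji <- sum(ifelse(lam >= 1, 1, 0) + lam - floor(lam))
  c(nyholt = nyholt, liji = liji)
}

# small helper: a minimal valid summary table built by hand
make_table <- function(df, trait = "t", type = "continuous") {
  col <- function(nm, default) if (nm %in% names(df)) df[[nm]] else default
  defaults <- tibble::tibble(
    variant_id = df$variant_id,
    chrom = col("chrom", "chr1"),
    pos = col("pos", seq(1e6, by = 1e4, length.out = nrow(df))),
    effect_allele = col("effect_allele", "A"),
    other_allele = col("other_allele", "C"),
    eaf = col("eaf", 0.3),
    beta = df$beta, se = df$se,
    pval = col("pval", pmax(2 * pnorm(-abs(df$beta / df$se)), 1e-320)),
    n = col("n", 10000),
    n_case = NA_real_, n_control = NA_real_
  )
  sumstats(defaults, trait_id = trait, trait_type = type)
}
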