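#' Wakefield log approximate Bayes factor
#'
#' Log approximate Bayes factor for a single variant's association, from its
#' effect estimate, standard error and a normal prior on the true effect:
#' with `V = se^2`, `W = prior_sd^2`, `r = W/(V + W)` and `z = beta/se`,
#' `lABF = 0.5 * (log(1 - r) + r * z^2)`.
#'
#' @param beta,se Effect estimate and standard error (`se > 0`); vectorized.
#' @param trait_type `"continuous"` (prior sd default 0.15 per SD) or
#'   `"case_control"` (default 0.2 on the log-odds scale).
#' @param prior_sd Override the effect-scale prior standard deviation.
#' @return Log Bayes factors.
#' @export
wakefield_labf <- function(beta, se,
                           trait_type = c("continuous", "case_control"),
                           prior_sd = NULL) {
  trait_type <- match.arg(trait_type)
  if (any(!(se > 0))) abort("se must be > 0", class = "protscreen_domain_error")
  prior_sd <- prior_sd %||% if (trait_type == "continuous") 0.15 else 0.2
  V <- se^2
  W <- prior_sd^2
  r <- W / (V + W)
  z <- beta / se
  0.5 * (log1p(-r) + r * z^2)
}

#' Colocalization priors
#'
#' Per-variant prior probabilities that a variant is causally associated with
#' trait 1 only (`p1`), trait 2 only (`p2`), or both (`p12`).
#'
#' @param p1,p2,p12 Priors in (0, 1).
#' @return A `coloc_priors` list.
#' @export
coloc_priors <- function(p1 = 1e-6, p2 = 1e-6, p12 = 1e-7) {
  for (p in c(p1, p2, p12)) {
    if (!(p > 0 && p < 1)) abort("priors must lie in (0,1)")
  }
  if (p12 > min(p1, p2)) {
    warn("p12 exceeds min(p1, p2); unusual prior configuration")
  }
  structure(list(p1 = p1, p2 = p2, p12 = p12), class = "coloc_priors")
}

# posterior over h0..h4 from per-variant log Bayes factors, all in log space
coloc_posteriors <- function(l1, l2, priors) {
  ls1 <- logsumexp(l1)
  ls2 <- logsumexp(l2)
  ls12 <- logsumexp(l1 + l2)
  L <- c(
    h0 = 0,
    h1 = log(priors$p1) + ls1,
    h2 = log(priors$p2) + ls2,
    # sum over ordered pairs i != j of BF1_i * BF2_j, computed stably as
    # (sum BF1)(sum BF2) - sum BF1*BF2 in log space
    h3 = log(priors$p1) + log(priors$p2) + logdiffexp(ls1 + ls2, ls12),
    h4 = log(priors$p12) + ls12
  )
  exp(L - logsumexp(L))
}

#' Single-causal-variant approximate-Bayes-factor colocalization
#'
#' Posterior probabilities of the five configurations of association sharing
#' in a region: no association (h0), trait 1 only (h1), trait 2 only (h2),
#' two distinct causal variants (h3), one shared causal variant (h4). Each
#' trait contributes per-variant Wakefield log Bayes factors; hypothesis
#' likelihoods are accumulated in log space and normalized. Orientation of
#' effects is irrelevant since z enters squared.
#'
#' @param trait1,trait2 Summary-statistic tibbles restricted to the region;
#'   only variants present in both are used.
#' @param priors A [coloc_priors()] object.
#' @param prior_sd1,prior_sd2 Optional effect-prior overrides per trait.
#' @return An object of class `coloc_result` with fields `h0`..`h4`,
#'   `n_variants`, `priors`, and (when set by [coloc_sensitivity_grid()])
#'   `window_bp`. Posteriors sum to 1 within 1e-9.
#' @export
coloc_abf <- function(trait1, trait2, priors = coloc_priors(),
                      prior_sd1 = NULL, prior_sd2 = NULL) {
  shared <- intersect(trait1$variant_id, trait2$variant_id)
  if (length(shared) == 0) {
    abort("no shared variants in region",
          class = "protscreen_empty_overlap_error")
  }
  t1 <- trait1[match(shared, trait1$variant_id), ]
  t2 <- trait2[match(shared, trait2$variant_id), ]
  l1 <- wakefield_labf(t1$beta, t1$se, trait_type(trait1), prior_sd1)
  l2 <- wakefield_labf(t2$beta, t2$se, trait_type(trait2), prior_sd2)
  if (length(shared) == 1) {
    ps_log("coloc_single_variant", note = "h3 undefined; assigned zero mass")
  }
  post <- coloc_posteriors(l1, l2, priors)
  structure(
    list(h0 = post[["h0"]], h1 = post[["h1"]], h2 = post[["h2"]],
         h3 = post[["h3"]], h4 = post[["h4"]],
         n_variants = length(shared), priors = priors, window_bp = NA_real_,
         trait1 = trait_id(trait1), trait2 = trait_id(trait2)),
    class = "coloc_result"
  )
}

#' @export
print.coloc_result <- function(x, ...) {
  cat(sprintf("<coloc_result> %s vs %s (%d variants)\n",
              x$trait1, x$trait2, x$n_variants))
  cat(sprintf("  h0 %.3f  h1 %.3f  h2 %.3f  h3 %.3f  h4 %.3f\n",
              x$h0, x$h1, x$h2, x$h3, x$h4))
  invisible(x)
}

#' Window and prior sensitivity grid for colocalization
#'
#' Repeats the colocalization over symmetric windows around the lead (index)
#' variant and over several prior sets, and issues a robustness verdict:
#' colocalization is called robust when h4 >= `h4_threshold` in the main cell
#' (the `main_window`, first prior set) AND in at least two non-main windows
#' (at the main priors) AND in at least one non-main prior set (at the main
#' window).
#'
#' @param trait1,trait2 Summary-statistic tibbles covering the region.
#' @param index_variant Lead variant around which windows are centred; must
#'   be present in `trait1`.
#' @param windows Window full widths in base pairs.
#' @param prior_sets List of [coloc_priors()]; the first is the main set.
#' @param main_window The main-analysis window (default 1 Mb).
#' @param h4_threshold Posterior threshold for calling colocalization.
#' @return An object of class `coloc_grid`: a tibble with one row per
#'   (window, prior set) cell plus attributes `robust` and `main_h4`.
#' @export
coloc_sensitivity_grid <- function(trait1, trait2, index_variant,
                                   windows = c(250e3, 500e3, 1e6, 2e6),
                                   prior_sets = list(
                                     coloc_priors(1e-6, 1e-6, 1e-7),
                                     coloc_priors(1e-5, 1e-5, 1e-6)
                                   ),
                                   main_window = 1e6, h4_threshold = 0.8) {
  idx <- trait1[trait1$variant_id == index_variant, ]
  if (nrow(idx) == 0) abort("index variant not present in trait1")
  cells <- tidyr::expand_grid(window_bp = windows,
                              prior_set = seq_along(prior_sets))
  rows <- pmap(cells, function(window_bp, prior_set) {
    pr <- prior_sets[[prior_set]]
    in_win <- trait1$chrom == idx$chrom &
      abs(trait1$pos - idx$pos) <= window_bp / 2
    t1 <- trait1[in_win, ]
    t2 <- trait2[trait2$variant_id %in% t1$variant_id, ]
    if (nrow(t1) == 0 || nrow(t2) == 0) {
      return(tibble(window_bp = window_bp, p1 = pr$p1, p2 = pr$p2,
                    p12 = pr$p12, n_variants = 0L, h0 = NA_real_,
                    h1 = NA_real_, h2 = NA_real_, h3 = NA_real_,
                    h4 = NA_real_, empty = TRUE))
    }
    # carry trait typing through the slice
    attr(t1, "trait_type") <- trait_type(trait1)
    attr(t2, "trait_type") <- trait_type(trait2)
    res <- coloc_abf(t1, t2, priors = pr)
    tibble(window_bp = window_bp, p1 = pr$p1, p2 = pr$p2, p12 = pr$p12,
           n_variants = res$n_variants, h0 = res$h0, h1 = res$h1,
           h2 = res$h2, h3 = res$h3, h4 = res$h4, empty = FALSE)
  })
  grid <- list_rbind(rows)
  main_cell <- grid[grid$window_bp == main_window &
                      grid$p12 == prior_sets[[1]]$p12 &
                      grid$p1 == prior_sets[[1]]$p1, ][1, ]
  pass <- function(h4) !is.na(h4) & h4 >= h4_threshold
  non_main_windows <- grid[grid$window_bp != main_window &
                             grid$p1 == prior_sets[[1]]$p1 &
                             grid$p12 == prior_sets[[1]]$p12, ]
  non_main_priors <- grid[grid$window_bp == main_window &
                            !(grid$p1 == prior_sets[[1]]$p1 &
                                grid$p12 == prior_sets[[1]]$p12), ]
  robust <- pass(main_cell$h4) &&
    sum(pass(non_main_windows$h4)) >= 2 &&
    (nrow(non_main_priors) == 0 || sum(pass(non_main_priors$h4)) >= 1)
  attr(grid, "robust") <- robust
  attr(grid, "main_h4") <- main_cell$h4
  attr(grid, "index_variant") <- index_variant
  attr(grid, "trait1") <- trait_id(trait1)
  attr(grid, "trait2") <- trait_id(trait2)
  class(grid) <- c("coloc_grid", class(grid))
  grid
}
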