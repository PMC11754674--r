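#' Harmonize exposure and outcome summary statistics to shared effect alleles
#'
#' Aligns the outcome table to the exposure's effect alleles over the shared
#' variants, so that each per-variant (beta_exp, beta_out) pair refers to the
#' same allele. When the outcome codes the alleles the other way round, its
#' beta is negated and its effect-allele frequency complemented; strand flips
#' (allele complements) are resolved the same way. Palindromic variants (A/T
#' or C/G) cannot be oriented from allele strings: they are aligned by
#' frequency matching, and dropped when the effect-allele frequency lies
#' within `palindrome_eaf_band` of 0.5 in either study (or is missing).
#'
#' When `proxies = TRUE`, exposure variants missing from the outcome are
#' substituted by their best LD proxy present in the outcome (see
#' [find_proxy()]); the proxy's outcome effect is oriented by the sign of r
#' and the variant is tagged `proxied`.
#'
#' @param exposure,outcome Summary-statistic tibbles (see [sumstats()]).
#' @param mediator Optional third table for three-way (MVMR) harmonization.
#' @param palindrome_eaf_band Half-width of the ambiguity band around 0.5.
#' @param proxies Substitute LD proxies for outcome-missing variants?
#' @param ld LD matrix, required when `proxies = TRUE`.
#' @param min_r2 Minimum proxy r-squared (see [find_proxy()]).
#' @return A tibble with columns `variant_id`, `beta_exp`, `se_exp`,
#'   `beta_out`, `se_out` (and `beta_med`, `se_med` when a mediator is given)
#'   and a per-variant `action` tag in
#'   `kept`/`flipped`/`dropped_palindromic`/`dropped_incompatible`/`proxied`.
#'   Dropped variants are retained as rows with `NA` effects so the
#'   harmonization record is complete; downstream estimators use
#'   [harmonized_effects()] to obtain the usable subset.
#' @export
harmonize <- function(exposure, outcome, mediator = NULL,
                      palindrome_eaf_band = 0.08,
                      proxies = FALSE, ld = NULL, min_r2 = 0.8) {
  out_tab <- outcome
  proxy_map <- character(0)
  if (proxies) {
    if (is.null(ld)) abort("proxies = TRUE requires an LD matrix")
    missing_ids <- setdiff(intersect(exposure$variant_id, ld_ids(ld)),
                           outcome$variant_id)
    for (v in missing_ids) {
      hit <- find_proxy(v, outcome, ld, min_r2 = min_r2)
      if (nrow(hit) == 0) next
      prx <- outcome[outcome$variant_id == hit$proxy, ]
      sgn <- sign(hit$r)
      exp_row <- exposure[exposure$variant_id == v, ]
      prx$variant_id <- v
      prx$chrom <- exp_row$chrom; prx$pos <- exp_row$pos
      prx$effect_allele <- exp_row$effect_allele
      prx$other_allele <- exp_row$other_allele
      prx$beta <- sgn * prx$beta
      prx$eaf <- ifelse(sgn >= 0, prx$eaf, 1 - prx$eaf)
      out_tab <- bind_rows(out_tab, prx)
      proxy_map <- c(proxy_map, v)
    }
  }
  shared <- intersect(exposure$variant_id, out_tab$variant_id)
  if (!is.null(mediator)) shared <- intersect(shared, mediator$variant_id)
  if (length(shared) == 0) {
    abort("no shared variants between exposure and outcome",
          class = "protscreen_empty_overlap_error")
  }
  e <- exposure[match(shared, exposure$variant_id), ]
  o <- out_tab[match(shared, out_tab$variant_id), ]

  al <- align_alleles(e, o, palindrome_eaf_band)
  res <- tibble(
    variant_id = shared,
    beta_exp = e$beta, se_exp = e$se,
    beta_out = ifelse(al$drop, NA_real_, ifelse(al$flip, -o$beta, o$beta)),
    se_out = ifelse(al$drop, NA_real_, o$se),
    action = al$action
  )
  if (!is.null(mediator)) {
    m <- mediator[match(shared, mediator$variant_id), ]
    alm <- align_alleles(e, m, palindrome_eaf_band)
    res$beta_med <- ifelse(alm$drop, NA_real_, ifelse(alm$flip, -m$beta, m$beta))
    res$se_med <- ifelse(alm$drop, NA_real_, m$se)
    res$action <- ifelse(alm$drop & !al$drop, alm$action, res$action)
    res$beta_out[alm$drop] <- NA_real_
  }
  res$action[res$variant_id %in% proxy_map & !is.na(res$beta_out)] <- "proxied"
  attr(res, "exposure_id") <- trait_id(exposure)
  attr(res, "outcome_id") <- trait_id(outcome)
  attr(res, "outcome_type") <- trait_type(outcome)
  if (!is.null(mediator)) attr(res, "mediator_id") <- trait_id(mediator)
  res
}

comp_allele <- function(a) c(A = "T", C = "G", G = "C", T = "A")[a]

is_palindromic <- function(ea, oa) {
  (ea == "A" & oa == "T") | (ea == "T" & oa == "A") |
    (ea == "C" & oa == "G") | (ea == "G" & oa == "C")
}

# orientation of table `o` relative to reference `e` (same variant order):
# returns flip/drop decisions and action tags
align_alleles <- function(e, o, band) {
  k <- nrow(e)
  flip <- logical(k); drop <- logical(k)
  action <- rep("kept", k)
  pal <- is_palindromic(e$effect_allele, e$other_allele)

  same <- e$effect_allele == o$effect_allele & e$other_allele == o$other_allele
  swap <- e$effect_allele == o$other_allele & e$other_allele == o$effect_allele
  csame <- comp_allele(e$effect_allele) == o$effect_allele &
    comp_allele(e$other_allele) == o$other_allele
  cswap <- comp_allele(e$effect_allele) == o$other_allele &
    comp_allele(e$other_allele) == o$effect_allele

  # non-palindromic: allele strings identify orientation
  np <- !pal
  flip[np & (swap | cswap)] <- TRUE
  bad <- np & !(same | swap | csame | cswap)
  drop[bad] <- TRUE
  action[np & flip] <- "flipped"
  action[bad] <- "dropped_incompatible"

  # palindromic: strings are uninformative; use frequency matching
  if (any(pal)) {
    ambiguous <- is.na(e$eaf) | is.na(o$eaf) |
      abs(e$eaf - 0.5) < band | abs(o$eaf - 0.5) < band
    pflip <- (e$eaf > 0.5) != (o$eaf > 0.5)
    drop[pal & ambiguous] <- TRUE
    action[pal & ambiguous] <- "dropped_palindromic"
    usable <- pal & !ambiguous
    flip[usable & pflip] <- TRUE
    action[usable & pflip] <- "flipped"
  }
  list(flip = flip & !drop, drop = drop, action = action)
}

#' Usable rows of a harmonized set
#'
#' @param h A harmonized tibble from [harmonize()].
#' @return Rows with complete exposure/outcome (and mediator) effects.
#' @export
harmonized_effects <- function(h) {
  cols <- intersect(c("beta_exp", "se_exp", "beta_out", "se_out",
                      "beta_med", "se_med"), names(h))
  out <- h[complete.cases(h[cols]), , drop = FALSE]
  for (a in c("exposure_id", "outcome_id", "mediator_id", "outcome_type")) {
    attr(out, a) <- attr(h, a)
  }
  out
}

#' Find the best LD proxy for a variant in an outcome table
#'
#' Among variants present in both `outcome` and the LD matrix, returns the one
#' with maximal squared correlation to `target`, provided r-squared reaches
#' `min_r2` (default 0.8). The signed r is returned so the proxy's effect can
#' be oriented to the target's coded allele.
#'
#' @param target Variant identifier; must be present in `ld`.
#' @param outcome A summary-statistic tibble.
#' @param ld LD matrix of signed correlations.
#' @param min_r2 Minimum acceptable squared correlation.
#' @return A one-row tibble `(target, proxy, r, r2)`, or a zero-row tibble
#'   when no candidate reaches `min_r2`.
#' @export
find_proxy <- function(target, outcome, ld, min_r2 = 0.8) {
  if (!target %in% ld_ids(ld)) {
    abort(paste0("variant not present in LD matrix: ", target),
          class = "protscreen_lookup_error")
  }
  cand <- intersect(outcome$variant_id, ld_ids(ld))
  empty <- tibble(target = character(0), proxy = character(0),
                  r = double(0), r2 = double(0))
  if (length(cand) == 0) return(empty)
  r <- ld_row(ld, target, cand)
  r2 <- r^2
  if (max(r2) < min_r2) return(empty)
  best <- which.max(r2)
  tibble(target = target, proxy = cand[best], r = unname(r[best]),
         r2 = unname(r2[best]))
}
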