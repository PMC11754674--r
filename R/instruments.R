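#' Per-variant F-statistic
#'
#' Instrument strength for a single variant, `F = (beta/se)^2`. An F above 10
#' is the conventional bar for a strong instrument.
#'
#' @param beta,se Effect estimate and its standard error (`se > 0`).
#' @return The F-statistic (vectorized).
#' @export
f_statistic <- function(beta, se) {
  if (any(!(se > 0))) abort("se must be > 0", class = "protscreen_domain_error")
  (beta / se)^2
}

#' Select genome-wide-significant, LD-independent instruments
#'
#' Filters to variants with `pval < p_threshold` (default 5e-8), clumps at the
#' `r2` threshold (default 0.001), and attaches per-variant F-statistics. The
#' instrument-set mean F is stored as an attribute; sets with mean F at or
#' below 10 are flagged weak but not excluded.
#'
#' @param table A summary-statistic tibble.
#' @param ld LD matrix.
#' @param p_threshold Selection p-value threshold.
#' @param r2 Clumping squared-correlation threshold.
#' @param window_kb Clumping window half-width (kilobases).
#' @return Surviving instrument rows with an added `F` column and attributes
#'   `selection_mode`, `mean_F` and `weak` (mean F <= 10). A zero-row tibble
#'   (with a warning) when nothing passes.
#' @export
select_genome_wide <- function(table, ld, p_threshold = 5e-8, r2 = 0.001,
                               window_kb = 10000) {
  hits <- filter(table, .data$pval < p_threshold)
  out <- ld_clump(hits, ld, r2_threshold = r2, window_kb = window_kb)
  finish_instruments(out, table, "genome_wide")
}

#' Select cis instruments around a gene's transcription start site
#'
#' Restricts the table to variants within `window_bp` of the gene's
#' transcription start site on the same chromosome, applies the cis p-value
#' threshold (default 1.8e-9), and clumps iteratively around the lead SNP of
#' the region. A protein without any passing cis variant yields an empty set
#' (recorded, not an error): such proteins are excluded from cis-MR.
#'
#' @param table A summary-statistic tibble (typically a protein GWAS).
#' @param gene A one-row data frame or list with `gene_id`, `chrom`, `tss`.
#' @param ld LD matrix.
#' @param p_threshold cis selection threshold.
#' @param window_bp Half-width of the cis window around the TSS (default 1 Mb).
#' @param r2 Clumping squared-correlation threshold.
#' @return As [select_genome_wide()], with `selection_mode = "cis"` and a
#'   `gene_id` attribute.
#' @export
select_cis <- function(table, gene, ld, p_threshold = 1.8e-9,
                       window_bp = 1e6, r2 = 0.001) {
  cis <- filter(table, .data$chrom == gene$chrom,
                abs(.data$pos - gene$tss) <= window_bp,
                .data$pval < p_threshold)
  # clump within the cis region itself: window spans the whole region
  out <- ld_clump(cis, ld, r2_threshold = r2,
                  window_kb = ceiling(2 * window_bp / 1000))
  out <- finish_instruments(out, table, "cis", warn_empty = FALSE)
  attr(out, "gene_id") <- gene$gene_id
  out
}

finish_instruments <- function(out, table, mode, warn_empty = TRUE) {
  if (nrow(out) == 0) {
    if (warn_empty) warn(paste0("no instruments selected for ", trait_id(table)))
    out$F <- double(0)
  } else {
    out$F <- f_statistic(out$beta, out$se)
  }
  attr(out, "selection_mode") <- mode
  attr(out, "mean_F") <- if (nrow(out)) mean(out$F) else NA_real_
  attr(out, "weak") <- isTRUE(attr(out, "mean_F") <= 10)
  attr(out, "trait_id") <- trait_id(table)
  attr(out, "trait_type") <- trait_type(table)
  if (isTRUE(attr(out, "weak"))) {
    ps_log("weak_instrument_set", trait = trait_id(table),
           mean_F = attr(out, "mean_F"))
  }
  out
}
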