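#' Greedy LD clumping by association p-value
#'
#' Repeatedly keeps the remaining variant with the smallest p-value and
#' removes all remaining variants whose squared correlation with it exceeds
#' `r2_threshold` within `window_kb` kilobases on the same chromosome. This is
#' the standard lead-SNP clumping used to obtain approximately LD-independent
#' instruments.
#'
#' Variants absent from the LD matrix cannot be assessed for independence and
#' are dropped with a warning rather than assumed independent.
#'
#' @param table A summary-statistic tibble.
#' @param ld LD matrix of signed correlations covering the table's variants.
#' @param r2_threshold Squared-correlation threshold (default 0.001).
#' @param window_kb Clumping window half-width in kilobases (default 10000).
#' @return The surviving rows, ordered by p-value. All pairwise r-squared
#'   values among survivors within the window are below the threshold.
#' @export
ld_clump <- function(table, ld, r2_threshold = 0.001, window_kb = 10000) {
  if (nrow(table) == 0) return(table)
  in_ld <- table$variant_id %in% ld_ids(ld)
  if (any(!in_ld)) {
    warn(paste0(sum(!in_ld), " variant(s) absent from the LD matrix dropped ",
                "during clumping (independence not assessable)"))
    ps_log("ld_clump_dropped", n = sum(!in_ld))
    table <- table[in_ld, , drop = FALSE]
  }
  if (nrow(table) == 0) return(table)
  tab <- arrange(table, .data$pval)
  keep <- character(0)
  remaining <- tab
  while (nrow(remaining) > 0) {
    lead <- remaining[1, ]
    keep <- c(keep, lead$variant_id)
    r2 <- ld_row(ld, lead$variant_id, remaining$variant_id)^2
    near <- remaining$chrom == lead$chrom &
      abs(remaining$pos - lead$pos) <= window_kb * 1000
    drop <- (near & r2 > r2_threshold) | remaining$variant_id == lead$variant_id
    remaining <- remaining[!drop, , drop = FALSE]
  }
  out <- tab[match(keep, tab$variant_id), , drop = FALSE]
  attr(out, "trait_id") <- trait_id(table)
  attr(out, "trait_type") <- trait_type(table)
  out
}
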