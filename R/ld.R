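#' Block-diagonal LD panels
#'
#' Large simulated panels are LD-independent across regions, so the full LD
#' matrix is block diagonal. `ld_blocks()` stores one dense correlation
#' matrix per region and serves cross-block correlations as exact zeros.
#' Both plain matrices and `ld_blocks` objects are accepted wherever the
#' package takes an LD argument.
#'
#' @param blocks Named list of symmetric correlation matrices with
#'   variant-id dimnames; variant ids must be globally unique.
#' @return An object of class `ld_blocks`.
#' @export
ld_blocks <- function(blocks) {
  ids <- unlist(lapply(blocks, rownames), use.names = FALSE)
  if (anyDuplicated(ids)) abort("variant ids must be unique across blocks")
  block_of <- rep(names(blocks), vapply(blocks, nrow, integer(1)))
  names(block_of) <- ids
  structure(list(blocks = blocks, ids = ids, block_of = block_of),
            class = "ld_blocks")
}

ld_ids <- function(ld) {
  if (inherits(ld, "ld_blocks")) ld$ids else rownames(ld)
}

# signed correlations between one variant and a set of variants
ld_row <- function(ld, id, ids) {
  if (!inherits(ld, "ld_blocks")) {
    return(ld[id, ids])
  }
  out <- setNames(numeric(length(ids)), ids)
  b <- ld$block_of[[id]]
  same <- ids[!is.na(ld$block_of[ids]) & ld$block_of[ids] == b]
  if (length(same)) out[same] <- ld$blocks[[b]][id, same]
  out
}

#' @export
print.ld_blocks <- function(x, ...) {
  cat(sprintf("<ld_blocks> %d variants in %d blocks\n",
              length(x$ids), length(x$blocks)))
  invisible(x)
}
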