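#' GWAS summary-statistic tables
#'
#' A summary-statistic table is a tibble with one row per variant and the
#' columns `variant_id`, `chrom`, `pos`, `effect_allele`, `other_allele`,
#' `eaf`, `beta`, `se`, `pval`, `n`, `n_case`, `n_control` (the last three may
#' be `NA` for continuous traits). Trait identity travels as the attributes
#' `trait_id` and `trait_type` (`"continuous"` or `"case_control"`). Effects
#' are per effect-allele copy: per normalized-SD units for continuous traits
#' (inverse-rank-normal scale) and log-odds for case-control traits.
#'
#' @param x A data frame with the columns above.
#' @param trait_id Character scalar naming the trait.
#' @param trait_type `"continuous"` or `"case_control"`.
#' @return A validated summary-statistic tibble.
#' @export
sumstats <- function(x, trait_id, trait_type = c("continuous", "case_control")) {
  trait_type <- match.arg(trait_type)
  x <- as_tibble(x)
  missing_cols <- setdiff(sumstats_cols(), names(x))
  if (length(missing_cols) > 0) {
    abort(paste0("missing mandatory column(s): ", paste(missing_cols, collapse = ", ")),
          class = "protscreen_format_error")
  }
  x <- x[sumstats_cols()]
  bad <- validate_sumstats_rows(x)
  if (length(bad$rows) > 0) {
    abort(
      paste0("invalid summary-statistic rows: ",
             paste(sprintf("row %d (%s)", bad$rows, bad$why), collapse = "; ")),
      class = "protscreen_validation_error", rows = bad$rows
    )
  }
  if (anyDuplicated(x$variant_id)) {
    abort("variant_id must be unique within a table",
          class = "protscreen_validation_error")
  }
  attr(x, "trait_id") <- trait_id
  attr(x, "trait_type") <- trait_type
  x
}

sumstats_cols <- function() {
  c("variant_id", "chrom", "pos", "effect_allele", "other_allele",
    "eaf", "beta", "se", "pval", "n", "n_case", "n_control")
}

validate_sumstats_rows <- function(x) {
  ok_allele <- function(a) a %in% c("A", "C", "G", "T")
  why <- character(0); rows <- integer(0)
  flag <- function(idx, msg) {
    rows <<- c(rows, idx); why <<- c(why, rep(msg, length(idx)))
  }
  flag(which(!(x$se > 0) | !is.finite(x$se)), "se must be > 0")
  flag(which(!is.na(x$eaf) & (x$eaf < 0 | x$eaf > 1)), "eaf outside [0,1]")
  flag(which(!(x$pval > 0 & x$pval <= 1)), "pval outside (0,1]")
  flag(which(!ok_allele(x$effect_allele) | !ok_allele(x$other_allele)),
       "alleles must be single nucleotides A/C/G/T")
  both <- !is.na(x$n_case) & !is.na(x$n_control) & !is.na(x$n)
  flag(which(both & x$n_case + x$n_control != x$n), "n_case + n_control != n")
  ord <- order(rows)
  list(rows = rows[ord], why = why[ord])
}

trait_id <- function(x) attr(x, "trait_id") %||% "trait"
trait_type <- function(x) attr(x, "trait_type") %||% "continuous"

#' Read a GWAS summary-statistic file
#'
#' Reads the package's tab-separated dialect: a header row with columns exactly
#' `variant_id chrom pos effect_allele other_allele eaf beta se pval n n_case
#' n_control`, missing values encoded as `NA`. Rows violating the record
#' invariants (non-positive `se`, `pval` outside (0,1], malformed alleles,
#' inconsistent case/control counts) are rejected with their line numbers.
#'
#' @param path Path to a tab-separated file.
#' @param trait_id Trait name; defaults to the file stem.
#' @param trait_type `"continuous"` or `"case_control"`.
#' @return A summary-statistic tibble (see [sumstats()]).
#' @export
read_sumstats <- function(path, trait_id = NULL,
                          trait_type = c("continuous", "case_control")) {
  trait_type <- match.arg(trait_type)
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "protscreen_format_error")
  }
  trait_id <- trait_id %||% sub("\\.[^.]*$", "", basename(path))
  raw <- readr::read_tsv(
    path, na = "NA", show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(
      variant_id = readr::col_character(), chrom = readr::col_character(),
      pos = readr::col_integer(), effect_allele = readr::col_character(),
      other_allele = readr::col_character(), eaf = readr::col_double(),
      beta = readr::col_double(), se = readr::col_double(),
      pval = readr::col_double(), n = readr::col_double(),
      n_case = readr::col_double(), n_control = readr::col_double()
    )
  )
  missing_cols <- setdiff(sumstats_cols(), names(raw))
  if (length(missing_cols) > 0) {
    abort(paste0("missing mandatory column(s) in ", path, ": ",
                 paste(missing_cols, collapse = ", ")),
          class = "protscreen_format_error")
  }
  out <- sumstats(raw, trait_id = trait_id, trait_type = trait_type)
  ps_log("read_sumstats", path = path, trait_id = trait_id,
         n_records = nrow(out), n_rejected = 0L)
  out
}

#' Write a summary-statistic table in the package dialect
#'
#' @param x A summary-statistic tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sumstats <- function(x, path) {
  readr::write_tsv(x[sumstats_cols()], path, na = "NA", progress = FALSE)
  invisible(path)
}

#' Read or write a signed LD correlation matrix
#'
#' The on-disk form is a square tab-separated matrix of signed correlations
#' `r` with variant identifiers as both header row and first column. The
#' matrix must be symmetric with a unit diagonal.
#'
#' @param path File path.
#' @return `read_ld_matrix()`: a numeric matrix with variant-id dimnames.
#' @export
read_ld_matrix <- function(path) {
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  ids <- as.character(raw[[1]])
  r <- as.matrix(raw[-1])
  rownames(r) <- ids
  validate_ld_matrix(r)
  ps_log("read_ld_matrix", path = path, n_variants = nrow(r))
  r
}

#' @rdname read_ld_matrix
#' @param r A symmetric correlation matrix with variant-id dimnames.
#' @export
write_ld_matrix <- function(r, path) {
  df <- as_tibble(r)
  df <- dplyr::bind_cols(tibble(variant_id = rownames(r)), df)
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

validate_ld_matrix <- function(r, tol = 1e-8) {
  if (!is.matrix(r) || nrow(r) != ncol(r)) {
    abort("LD matrix must be square", class = "protscreen_validation_error")
  }
  if (is.null(rownames(r))) rownames(r) <- colnames(r)
  if (max(abs(r - t(r))) > tol) {
    abort("LD matrix must be symmetric", class = "protscreen_validation_error")
  }
  if (max(abs(diag(r) - 1)) > tol) {
    abort("LD matrix diagonal must be 1", class = "protscreen_validation_error")
  }
  invisible(r)
}

# JSON-lines run log; active when options(protscreen.log_file=) is set
ps_log <- function(event, ...) {
  path <- getOption("protscreen.log_file", NULL)
  if (is.null(path)) return(invisible(NULL))
  rec <- c(list(time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), event = event),
           list(...))
  cat(jsonlite::toJSON(rec, auto_unbox = TRUE), "\n", sep = "",
      file = path, append = TRUE)
  invisible(NULL)
}
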