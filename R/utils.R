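#' nd-aware arithmetic mean
#'
#' Arithmetic mean over the non-missing ("detected") values of `x`. Returns
#' `NA` when every value is missing — a protein not detected in any replicate
#' stays not detected, it does not become zero.
#'
#' @param x Numeric vector; `NA` marks an nd (not detected) measurement.
#' @return A length-one numeric, or `NA` if all of `x` is `NA`.
#' @examples
#' nd_mean(c(2, 4, 6))
#' nd_mean(c(2, NA, 6))
#' nd_mean(c(NA, NA))
#' @export
nd_mean <- function(x) {
  if (all(is.na(x))) return(NA_real_)
  mean(x, na.rm = TRUE)
}

# Average per-replicate values within one experiment (nd-excluded).
#' @rdname nd_mean
#' @export
average_over_replicates <- function(x) nd_mean(x)

# Average per-experiment values (nd-excluded), as used for the final
# TOP3 abundance column.
#' @rdname nd_mean
#' @export
average_over_experiments <- function(x) nd_mean(x)

# Scientific notation with 3 significant digits, "5.20E+07" style.
format_abundance <- function(x) {
  out <- toupper(formatC(x, format = "e", digits = 2))
  out[is.na(x)] <- "nd"
  out
}

format_ratio <- function(x, digits = 1) {
  out <- formatC(x, format = "f", digits = digits)
  out[is.infinite(x)] <- "Inf"
  out[is.na(x)] <- "nd"
  out
}

# Semicolon conventions for accession sets inside a single table cell.
split_accessions <- function(x) strsplit(x, ";", fixed = TRUE)
join_accessions <- function(x) vapply(x, paste, character(1), collapse = ";")

sample_id <- function(fraction, experiment, replicate) {
  paste(fraction, experiment, replicate, sep = "_")
}
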