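#' Read a peptide-level quantification table
#'
#' Reads the long-format peptide table the pipeline consumes: one row per
#' (peptide, sample) with columns `peptide_id`, `accessions` (semicolon-joined
#' protein accessions), `fraction`, `experiment`, `replicate`, `abundance`.
#' The tokens `nd`, `NA` and empty cells all parse to the nd marker (`NA`);
#' abundances in scientific notation (e.g. `4.47E+04`) are accepted. A wide
#' dialect (one abundance column per sample, named `<fraction>_<exp>_<rep>`)
#' is accepted on read only and pivoted to long form.
#'
#' Validation names the offending rows: duplicated (peptide, sample) keys,
#' fraction labels outside `fraction_set`, and negative abundances are all
#' format errors.
#'
#' @param path File path.
#' @param fraction_set Declared fraction labels; rows with other labels fail.
#' @param dialect One of `"long_tsv"`, `"long_csv"`, `"wide_tsv"`.
#' @param quiet Suppress the per-sample row/nd count log.
#' @return A validated tibble (`peptide_quant` class).
#' @export
read_peptide_table <- function(path, fraction_set = c("LD", "SOL", "MEM", "TL", "PG"),
                               dialect = c("long_tsv", "long_csv", "wide_tsv"),
                               quiet = FALSE) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) {
    abort(sprintf("File not found: %s", path), class = "coreome_io_error")
  }
  reader <- if (dialect == "long_csv") readr::read_csv else readr::read_tsv
  raw <- reader(path, col_types = readr::cols(.default = readr::col_character()),
                progress = FALSE)
  if (dialect == "wide_tsv") {
    raw <- tidyr::pivot_longer(raw, cols = -c("peptide_id", "accessions"),
                               names_to = c("fraction", "experiment", "replicate"),
                               names_pattern = "^(.+)_(\\d+)_(\\d+)$",
                               values_to = "abundance")
  }
  needed <- c("peptide_id", "accessions", "fraction", "experiment", "replicate",
              "abundance")
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols)) {
    abort(sprintf("Missing column(s): %s", paste(missing_cols, collapse = ", ")),
          class = "coreome_format_error")
  }
  tab <- tibble::tibble(
    peptide_id = raw$peptide_id,
    accessions = raw$accessions,
    fraction = raw$fraction,
    experiment = as.integer(raw$experiment),
    replicate = as.integer(raw$replicate),
    abundance = parse_abundance(raw$abundance)
  )
  validate_peptide_table(tab, fraction_set)
  if (!quiet) {
    log_tab <- dplyr::summarise(
      dplyr::group_by(tab, .data$fraction, .data$experiment, .data$replicate),
      n = dplyr::n(), nd = sum(is.na(.data$abundance)), .groups = "drop")
    inform(sprintf("Read %d rows, %d samples; nd rate %.1f%%",
                   nrow(tab), nrow(log_tab),
                   100 * sum(log_tab$nd) / max(1, nrow(tab))))
  }
  class(tab) <- c("peptide_quant", class(tab))
  tab
}

parse_abundance <- function(x) {
  x <- trimws(x)
  miss <- is.na(x) | x == "" | tolower(x) %in% c("nd", "na")
  out <- suppressWarnings(as.numeric(x))
  bad <- !miss & is.na(out)
  if (any(bad)) {
    abort(sprintf("Unparseable abundance in row(s): %s",
                  paste(head(which(bad), 5), collapse = ", ")),
          class = "coreome_format_error")
  }
  out[miss] <- NA_real_
  out
}

validate_peptide_table <- function(tab, fraction_set) {
  bad_frac <- which(!tab$fraction %in% fraction_set)
  if (length(bad_frac)) {
    abort(sprintf("Unknown fraction label in row(s): %s",
                  paste(head(bad_frac, 5), collapse = ", ")),
          class = "coreome_format_error")
  }
  neg <- which(!is.na(tab$abundance) & tab$abundance < 0)
  if (length(neg)) {
    abort(sprintf("Negative abundance in row(s): %s",
                  paste(head(neg, 5), collapse = ", ")),
          class = "coreome_format_error")
  }
  key <- paste(tab$peptide_id, tab$fraction, tab$experiment, tab$replicate)
  dup <- which(duplicated(key))
  if (length(dup)) {
    abort(sprintf("Duplicate (peptide, sample) in row(s): %s",
                  paste(head(dup, 5), collapse = ", ")),
          class = "coreome_format_error")
  }
  bad_acc <- which(is.na(tab$accessions) | !nzchar(tab$accessions))
  if (length(bad_acc)) {
    abort(sprintf("Empty accession in row(s): %s",
                  paste(head(bad_acc, 5), collapse = ", ")),
          class = "coreome_format_error")
  }
  invisible(tab)
}

#' Write a peptide quantification table as TSV
#'
#' Long-format TSV with nd measurements written as the literal token `nd`;
#' abundances are written at full precision so that a write/read round trip
#' is lossless.
#'
#' @param table Peptide table tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_peptide_table <- function(table, path) {
  out <- dplyr::mutate(table, abundance = ifelse(
    is.na(.data$abundance), "nd",
    formatC(.data$abundance, format = "g", digits = 17)))
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Read annotation lists
#'
#' Loads the two accession lists the core-proteome call consults: the known
#' contaminant-organelle reference (e.g. established plastoglobule proteins,
#' used to calibrate the contaminant exclusion ratio) and prior exclusions
#' (accessions with a previously characterized non-target localization),
#' plus an optional accession-to-category map. Files hold one accession per
#' line with an optional tab-separated second column; lists are de-duplicated
#' and overlap between the two lists is permitted (and reported).
#'
#' @param contaminant_path,exclusion_path,category_path File paths; `NULL`
#'   for an empty list.
#' @param quiet Suppress the overlap log message.
#' @return An `annotation_lists` object; see [annotation_lists()].
#' @export
read_annotation_lists <- function(contaminant_path = NULL, exclusion_path = NULL,
                                  category_path = NULL, quiet = FALSE) {
  read_set <- function(p) {
    if (is.null(p)) return(character(0))
    if (!file.exists(p)) abort(sprintf("File not found: %s", p),
                               class = "coreome_io_error")
    lines <- readr::read_lines(p, progress = FALSE)
    lines <- trimws(vapply(strsplit(lines, "\t", fixed = TRUE),
                           function(x) if (length(x)) x[1] else "", character(1)))
    unique(lines[nzchar(lines)])
  }
  cat_map <- NULL
  if (!is.null(category_path)) {
    if (!file.exists(category_path)) {
      abort(sprintf("File not found: %s", category_path), class = "coreome_io_error")
    }
    cm <- readr::read_tsv(category_path, col_names = c("accession", "category"),
                          col_types = "cc", progress = FALSE)
    cat_map <- dplyr::distinct(cm, .data$accession, .keep_all = TRUE)
  }
  annotation_lists(contaminant_reference = read_set(contaminant_path),
                   prior_exclusions = read_set(exclusion_path),
                   category_map = cat_map, quiet = quiet)
}

#' Construct annotation lists in code
#'
#' @param contaminant_reference Accessions of known contaminant-organelle
#'   residents.
#' @param prior_exclusions Accessions with prior non-target localization.
#' @param category_map Optional tibble (`accession`, `category`).
#' @param quiet Suppress the overlap log message.
#' @return An `annotation_lists` object.
#' @export
annotation_lists <- function(contaminant_reference = character(0),
                             prior_exclusions = character(0),
                             category_map = NULL, quiet = TRUE) {
  both <- intersect(contaminant_reference, prior_exclusions)
  if (length(both) && !quiet) {
    inform(sprintf("%d accession(s) appear in both annotation lists", length(both)))
  }
  structure(list(contaminant_reference = unique(contaminant_reference),
                 prior_exclusions = unique(prior_exclusions),
                 category_map = category_map),
            class = "annotation_lists")
}

#' Write the core-proteome report tables
#'
#' Emits two plain TSVs: an enrichment report (per-experiment ratios of the
#' target fraction over soluble, membrane and total-leaf references, the
#' contaminant ratio, per-experiment pass flags, the number of passing
#' experiments, final status and exclusion reason) and an abundance report
#' (per-experiment TOP3 values, the nd-aware average, and the mass
#' contribution in percent). Abundances are formatted in scientific notation
#' with 3 significant digits, ratios with 1 decimal, percentages with 2.
#'
#' @param result A [call_core_proteome()] result.
#' @param top3_summary A [top3_summary()] tibble (may cover core groups only).
#' @param dir Output directory, created if needed.
#' @return Paths of the two files, invisibly.
#' @export
write_core_report <- function(result, top3_summary, dir) {
  if (!inherits(result, "core_call")) {
    abort("`result` must come from call_core_proteome().",
          class = "coreome_consistency_error")
  }
  extra <- setdiff(top3_summary$group_id, result$result$group_id)
  if (length(extra)) {
    abort(sprintf("TOP3 summary has group(s) absent from the filter result: %s",
                  paste(head(extra, 5), collapse = ", ")),
          class = "coreome_consistency_error")
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)

  prof <- result$profiles
  wide <- tidyr::pivot_wider(
    dplyr::select(prof, "group_id", "experiment", "e_sol", "e_mem", "e_tl"),
    names_from = "experiment",
    values_from = c("e_sol", "e_mem", "e_tl"),
    names_glue = "exp{experiment}_{.value}")
  pg <- dplyr::summarise(dplyr::group_by(prof, .data$group_id),
                         e_pg = if (all(is.na(.data$e_pg))) NA_real_ else
                           max(.data$e_pg, na.rm = TRUE), .groups = "drop")
  enr <- dplyr::left_join(result$result, wide, by = "group_id")
  enr <- dplyr::left_join(enr, pg, by = "group_id")
  enr <- dplyr::mutate(enr,
    dplyr::across(dplyr::starts_with("exp"), format_ratio),
    e_pg = format_ratio(.data$e_pg),
    reason = dplyr::case_when(
      .data$status == "core" ~ "",
      .data$status == "fail_experiments" ~ "criteria_not_met_in_k_experiments",
      .data$status == "excluded_contaminant" ~ "contaminant_fraction",
      .data$status == "excluded_prior" ~ "prior_localization"))
  enr_path <- file.path(dir, "core_proteome_report.tsv")
  readr::write_tsv(enr, enr_path, progress = FALSE)

  ab <- dplyr::mutate(top3_summary,
    dplyr::across(dplyr::starts_with("top3_exp"), format_abundance),
    average = format_abundance(.data$average),
    mass_contribution = ifelse(is.na(.data$mass_contribution), "nd",
                               formatC(.data$mass_contribution, format = "f",
                                       digits = 2)))
  ab_path <- file.path(dir, "top3_abundance_report.tsv")
  readr::write_tsv(ab, ab_path, progress = FALSE)
  invisible(c(enr_path, ab_path))
}
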