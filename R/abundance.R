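#' Per-sample protein abundance for every quantifiable group
#'
#' Computes, for each quantifiable protein group and each sample, either the
#' uniqueness-based abundance (`unique_sum`: sum of the group's unique
#' peptides measured in the sample — the estimator for between-sample
#' comparison) or the TOP3 / Hi-3 abundance (`top3`: sum of the three most
#' abundant unique peptides measured in the sample — proportional to molar
#' amount, the estimator for within-sample comparison). With fewer than
#' three measured peptides TOP3 sums what exists and flags it
#' (`n_top_used < 3`) rather than returning nd; a group with no measured
#' unique peptide in a sample is nd there. Non-quantifiable groups are
#' skipped with a warning.
#'
#' TOP3 is computed over unique peptides only: shared peptides would count
#' the same ion signal toward several groups and break the 100% mass
#' normalization.
#'
#' @param table Peptide quantification table.
#' @param groups Output of [build_groups()].
#' @param mode `"unique_sum"` or `"top3"`.
#' @return Long tibble `group_id`, `fraction`, `experiment`, `replicate`,
#'   `abundance` (`NA` = nd), `n_used` (peptides entering the sum), with a
#'   `mode` attribute.
#' @export
abundance_matrix <- function(table, groups, mode = c("unique_sum", "top3")) {
  mode <- match.arg(mode)
  skipped <- groups$group_id[!groups$quantifiable]
  if (length(skipped)) {
    warn(sprintf("Skipping %d non-quantifiable group(s): %s",
                 length(skipped), paste(head(skipped, 5), collapse = ", ")))
  }
  q <- groups[groups$quantifiable, , drop = FALSE]
  pep2grp <- tibble::tibble(
    group_id = rep(q$group_id, lengths(q$unique_peptides)),
    peptide_id = unlist(q$unique_peptides))
  samples <- dplyr::distinct(table, .data$fraction, .data$experiment, .data$replicate)

  measured <- dplyr::inner_join(
    dplyr::filter(table, !is.na(.data$abundance)), pep2grp,
    by = "peptide_id", relationship = "many-to-many")
  agg <- dplyr::summarise(
    dplyr::group_by(measured, .data$group_id, .data$fraction,
                    .data$experiment, .data$replicate),
    abundance = if (mode == "top3") {
      sum(sort(.data$abundance, decreasing = TRUE)[seq_len(min(3L, dplyr::n()))])
    } else {
      sum(.data$abundance)
    },
    n_used = if (mode == "top3") min(3L, dplyr::n()) else dplyr::n(),
    .groups = "drop")

  full <- tidyr::expand_grid(group_id = q$group_id, samples)
  out <- dplyr::left_join(full, agg,
                          by = c("group_id", "fraction", "experiment", "replicate"))
  out$n_used[is.na(out$n_used)] <- 0L
  out <- dplyr::arrange(out, .data$group_id, .data$fraction,
                        .data$experiment, .data$replicate)
  attr(out, "mode") <- mode
  out
}

#' Protein abundance in a single sample
#'
#' Scalar convenience wrapper around [abundance_matrix()] for one group in
#' one sample.
#'
#' @inheritParams abundance_matrix
#' @param group_id Group identifier.
#' @param fraction,experiment,replicate Sample coordinates.
#' @return A single abundance value, or `NA` (nd) if no unique peptide of
#'   the group is measured in the sample.
#' @export
protein_abundance <- function(table, groups, group_id, fraction, experiment,
                              replicate, mode = c("unique_sum", "top3")) {
  mode <- match.arg(mode)
  mat <- abundance_matrix(table, groups, mode)
  hit <- mat[mat$group_id == group_id & mat$fraction == fraction &
               mat$experiment == experiment & mat$replicate == replicate, ]
  if (nrow(hit) == 0) {
    abort(sprintf("Sample (%s, %s, %s) or group %s not present.",
                  fraction, experiment, replicate, group_id),
          class = "coreome_input_error")
  }
  hit$abundance
}

#' Relative normalized abundance
#'
#' Divides each group's per-sample abundance by the summed abundance of
#' *all* measured peptides in that sample — including shared, ungrouped and
#' non-quantifiable peptides — so the value is the group's share of the
#' total peptide signal of the sample (its relative mass contribution).
#' Samples are thereby put on a common scale: multiplying every abundance
#' in a sample by a constant leaves every `rel_abundance` unchanged.
#'
#' @inheritParams abundance_matrix
#' @return Tibble like [abundance_matrix()] with an extra `rel_abundance`
#'   column in \[0, 1\] (`NA` = nd).
#' @export
relative_abundance <- function(table, groups, mode = c("unique_sum", "top3")) {
  mode <- match.arg(mode)
  totals <- dplyr::summarise(
    dplyr::group_by(table, .data$fraction, .data$experiment, .data$replicate),
    total = sum(.data$abundance, na.rm = TRUE),
    n_measured = sum(!is.na(.data$abundance)), .groups = "drop")
  dead <- totals[totals$n_measured == 0, ]
  if (nrow(dead)) {
    abort(sprintf("Sample with no measured peptide: %s",
                  paste(sample_id(dead$fraction, dead$experiment, dead$replicate),
                        collapse = ", ")),
          class = "coreome_input_error")
  }
  mat <- abundance_matrix(table, groups, mode)
  out <- dplyr::left_join(mat, totals[, c("fraction", "experiment", "replicate",
                                          "total")],
                          by = c("fraction", "experiment", "replicate"))
  out$rel_abundance <- out$abundance / out$total
  out$total <- NULL
  attr(out, "mode") <- mode
  out
}

#' Mass contribution percentages
#'
#' Rescales a vector of (experiment-averaged) abundances to percentages of
#' their defined total: `100 * x / sum(x, nd excluded)`. Entries that are nd
#' stay nd. The defined entries sum to exactly 100 before rounding.
#'
#' @param averages Numeric vector (`NA` = nd).
#' @return Percentages, same length as `averages`.
#' @examples
#' mass_contribution(c(75, 25))
#' @export
mass_contribution <- function(averages) {
  if (all(is.na(averages))) {
    abort("All averages are nd; no mass contribution defined.",
          class = "coreome_input_error")
  }
  100 * averages / sum(averages, na.rm = TRUE)
}

#' TOP3 abundance summary per group
#'
#' Builds the within-target-fraction abundance summary: for each
#' quantifiable group, the TOP3 abundance per sample of the target fraction,
#' averaged over technical replicates within each experiment (nd excluded),
#' then over experiments (nd excluded), and finally each group's mass
#' contribution as a percent of the summed averages.
#'
#' Two conventions for the percentage column exist in practice and are both
#' available: the default `"percent_of_averages"` computes percentages from
#' the experiment-averaged abundances; `"average_of_percents"` computes a
#' per-sample percentage first and averages those.
#'
#' @inheritParams abundance_matrix
#' @param target_fraction Fraction the summary describes (default `"LD"`).
#' @param convention `"percent_of_averages"` (default) or
#'   `"average_of_percents"`.
#' @return A `top3_summary` tibble: `group_id`, `members`, one
#'   `top3_exp<e>` column per experiment, `average`, `mass_contribution`.
#' @export
top3_summary <- function(table, groups, target_fraction = "LD",
                         convention = c("percent_of_averages",
                                        "average_of_percents")) {
  convention <- match.arg(convention)
  mat <- abundance_matrix(table, groups, "top3")
  mat <- dplyr::filter(mat, .data$fraction == target_fraction)
  if (nrow(mat) == 0) {
    abort(sprintf("No samples of target fraction '%s'.", target_fraction),
          class = "coreome_input_error")
  }
  per_exp <- dplyr::summarise(
    dplyr::group_by(mat, .data$group_id, .data$experiment),
    top3 = nd_mean(.data$abundance), .groups = "drop")
  wide <- tidyr::pivot_wider(per_exp, names_from = "experiment",
                             values_from = "top3", names_prefix = "top3_exp")
  exp_cols <- grep("^top3_exp", names(wide), value = TRUE)
  wide$average <- apply(wide[exp_cols], 1, nd_mean)

  if (convention == "percent_of_averages") {
    wide$mass_contribution <- mass_contribution(wide$average)
  } else {
    per_sample <- dplyr::ungroup(dplyr::mutate(
      dplyr::group_by(mat, .data$experiment, .data$replicate),
      pct = 100 * .data$abundance / sum(.data$abundance, na.rm = TRUE)))
    mc <- dplyr::summarise(dplyr::group_by(per_sample, .data$group_id),
                           mass_contribution = nd_mean(.data$pct),
                           .groups = "drop")
    wide <- dplyr::left_join(wide, mc, by = "group_id")
  }
  out <- dplyr::left_join(wide,
                          groups[, c("group_id", "members")], by = "group_id")
  out <- dplyr::select(out, "group_id", "members", dplyr::all_of(exp_cols),
                       "average", "mass_contribution")
  out <- dplyr::arrange(out, dplyr::desc(.data$mass_contribution))
  class(out) <- c("top3_summary", class(out))
  attr(out, "convention") <- convention
  out
}
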