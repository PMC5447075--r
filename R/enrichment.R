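#' Filter criteria for the core-proteome call
#'
#' The thresholds and k-of-n rule applied to per-experiment enrichment
#' ratios. Strictness follows the published convention: the target/total
#' ratio must be *strictly greater* than `t_total`; ratios over the soluble,
#' membrane and contaminant references keep values *equal to* their
#' thresholds (only strictly smaller values are discarded). Defaults
#' reproduce the lipid-droplet study settings: target/total > 6,
#' target/soluble and target/membrane >= 1.5, target/contaminant >= 4,
#' in at least 2 of 3 independent experiments.
#'
#' @param t_total Threshold on the target/total-extract ratio (strict `>`).
#' @param t_soluble,t_membrane Thresholds on target/soluble and
#'   target/membrane (non-strict: equal values are kept).
#' @param t_contaminant Threshold on target/contaminant-organelle
#'   (non-strict: equal values are kept; smaller flags the group as a
#'   contaminant).
#' @param k_required Experiments that must pass all per-experiment criteria.
#' @param n_experiments Total number of independent experiments.
#' @return A `filter_criteria` object.
#' @export
filter_criteria <- function(t_total = 6, t_soluble = 1.5, t_membrane = 1.5,
                            t_contaminant = 4, k_required = 2,
                            n_experiments = 3) {
  vals <- c(t_total = t_total, t_soluble = t_soluble,
            t_membrane = t_membrane, t_contaminant = t_contaminant)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    abort("All thresholds must be finite and > 0.",
          class = "coreome_config_error")
  }
  if (k_required < 1 || k_required > n_experiments) {
    abort("`k_required` must satisfy 1 <= k_required <= n_experiments.",
          class = "coreome_config_error")
  }
  structure(list(t_total = t_total, t_soluble = t_soluble,
                 t_membrane = t_membrane, t_contaminant = t_contaminant,
                 k_required = as.integer(k_required),
                 n_experiments = as.integer(n_experiments)),
            class = "filter_criteria")
}

#' @export
print.filter_criteria <- function(x, ...) {
  cat(sprintf(paste0("Core-proteome filter criteria:\n",
                     "  target/total     > %g\n",
                     "  target/soluble  >= %g\n",
                     "  target/membrane >= %g\n",
                     "  target/contaminant >= %g\n",
                     "  required in %d of %d experiments\n"),
              x$t_total, x$t_soluble, x$t_membrane, x$t_contaminant,
              x$k_required, x$n_experiments))
  invisible(x)
}

# ratio with the enrichment conventions: nd target => nd; measured target
# over an absent or zero reference => Inf (absence from a reference fraction
# is maximal enrichment evidence)
safe_ratio <- function(num, den) {
  dplyr::case_when(
    is.na(num) ~ NA_real_,
    (is.na(den) | den == 0) & num > 0 ~ Inf,
    is.na(den) | den == 0 ~ NA_real_,
    TRUE ~ num / den)
}

#' Per-experiment enrichment ratios of the target fraction
#'
#' For each protein group and each experiment, averages the relative
#' normalized abundance over technical replicates (nd excluded) within each
#' fraction, then forms the ratio of the target-fraction average over the
#' average in each reference fraction: soluble (`e_sol`), membrane
#' (`e_mem`), total extract (`e_tl`), and — only for experiments where a
#' contaminant-organelle sample exists — contaminant (`e_pg`).
#'
#' A ratio is nd (`NA`) when the target average is nd; it is `Inf` when the
#' target is measured but the reference average is nd or zero (absence from
#' a reference is maximal enrichment evidence and passes any threshold).
#' The variant `ratio_of_averages = FALSE` forms per-replicate ratios first
#' and averages those instead.
#'
#' @param rel Output of [relative_abundance()] with `mode = "unique_sum"`
#'   (the between-sample estimator).
#' @param target_fraction,soluble,membrane,total,contaminant Fraction labels.
#' @param ratio_of_averages If `TRUE` (default) average replicates then take
#'   the ratio; if `FALSE`, take per-replicate ratios then average.
#' @return Tibble `group_id`, `experiment`, `e_sol`, `e_mem`, `e_tl`, `e_pg`.
#' @export
enrichment_ratios <- function(rel, target_fraction = "LD", soluble = "SOL",
                              membrane = "MEM", total = "TL",
                              contaminant = "PG", ratio_of_averages = TRUE) {
  mode <- attr(rel, "mode")
  if (!is.null(mode) && mode != "unique_sum") {
    warn("Enrichment ratios are defined on the unique_sum estimator; got a different mode.")
  }
  roles <- c(target_fraction, soluble, membrane, total, contaminant)
  pg_exps <- unique(rel$experiment[rel$fraction == contaminant])

  if (ratio_of_averages) {
    rbar <- dplyr::summarise(
      dplyr::group_by(rel, .data$group_id, .data$fraction, .data$experiment),
      r = nd_mean(.data$rel_abundance), .groups = "drop")
    wide <- tidyr::pivot_wider(dplyr::filter(rbar, .data$fraction %in% roles),
                               names_from = "fraction", values_from = "r")
    for (f in setdiff(roles, names(wide))) wide[[f]] <- NA_real_
    out <- tibble::tibble(
      group_id = wide$group_id, experiment = wide$experiment,
      e_sol = safe_ratio(wide[[target_fraction]], wide[[soluble]]),
      e_mem = safe_ratio(wide[[target_fraction]], wide[[membrane]]),
      e_tl = safe_ratio(wide[[target_fraction]], wide[[total]]),
      e_pg = ifelse(wide$experiment %in% pg_exps,
                    safe_ratio(wide[[target_fraction]], wide[[contaminant]]),
                    NA_real_))
  } else {
    wide <- tidyr::pivot_wider(
      dplyr::filter(rel, .data$fraction %in% roles)[
        , c("group_id", "fraction", "experiment", "replicate", "rel_abundance")],
      names_from = "fraction", values_from = "rel_abundance")
    for (f in setdiff(roles, names(wide))) wide[[f]] <- NA_real_
    per_rep <- tibble::tibble(
      group_id = wide$group_id, experiment = wide$experiment,
      e_sol = safe_ratio(wide[[target_fraction]], wide[[soluble]]),
      e_mem = safe_ratio(wide[[target_fraction]], wide[[membrane]]),
      e_tl = safe_ratio(wide[[target_fraction]], wide[[total]]),
      e_pg = ifelse(wide$experiment %in% pg_exps,
                    safe_ratio(wide[[target_fraction]], wide[[contaminant]]),
                    NA_real_))
    out <- dplyr::summarise(
      dplyr::group_by(per_rep, .data$group_id, .data$experiment),
      dplyr::across(c("e_sol", "e_mem", "e_tl", "e_pg"), nd_mean),
      .groups = "drop")
  }
  dplyr::arrange(out, .data$group_id, .data$experiment)
}

#' Does a group pass the per-experiment criteria?
#'
#' True iff the target/total ratio strictly exceeds `t_total` *and* the
#' target/soluble and target/membrane ratios are at least their thresholds.
#' `Inf` passes any threshold; nd (`NA`) fails. Vectorized over experiments.
#'
#' @param e_sol,e_mem,e_tl Enrichment ratios for one or more experiments.
#' @param criteria A [filter_criteria()].
#' @return Logical vector.
#' @examples
#' passes_experiment(12.0, 1.5, 8.3, filter_criteria())  # kept: 1.5 is not < 1.5
#' passes_experiment(2.8, 40.2, 3.1, filter_criteria())  # fails: 3.1 <= 6
#' @export
passes_experiment <- function(e_sol, e_mem, e_tl, criteria = filter_criteria()) {
  ok <- e_tl > criteria$t_total & e_sol >= criteria$t_soluble &
    e_mem >= criteria$t_membrane
  ok & !is.na(ok)
}

#' Call the core proteome from enrichment profiles
#'
#' Applies the full multi-criteria decision to every group: counts the
#' experiments whose ratios satisfy [passes_experiment()] (nd experiments
#' count as failed), flags groups whose every available contaminant ratio is
#' below `t_contaminant` (a missing contaminant ratio never excludes), flags
#' groups with a prior non-target localization from the annotation list, and
#' assigns `status`: `core` iff at least `k_required` experiments pass and
#' neither exclusion flag is set; otherwise `fail_experiments`,
#' `excluded_contaminant`, or `excluded_prior` (in that precedence).
#'
#' @param profiles Output of [enrichment_ratios()], or any tibble with
#'   columns `group_id`, `experiment`, `e_sol`, `e_mem`, `e_tl`, `e_pg`
#'   (this is the injection point for externally computed ratio tables).
#' @param criteria A [filter_criteria()].
#' @param annotations Optional [annotation_lists()].
#' @param groups Optional [build_groups()] output supplying group membership
#'   (used for the prior-exclusion match and reporting); defaults to
#'   `members = group_id`.
#' @return A `core_call` object: list with `result` (tibble `group_id`,
#'   `members`, `n_pass`, `contaminant_flag`, `prior_exclusion_flag`,
#'   `status`), `passes` (per-experiment flags), `profiles`, `criteria`.
#' @export
call_core_proteome <- function(profiles, criteria = filter_criteria(),
                               annotations = NULL, groups = NULL) {
  if (!inherits(criteria, "filter_criteria")) {
    abort("`criteria` must be built with filter_criteria().",
          class = "coreome_config_error")
  }
  need <- c("group_id", "experiment", "e_sol", "e_mem", "e_tl")
  if (!all(need %in% names(profiles))) {
    abort(sprintf("`profiles` must have columns %s.", paste(need, collapse = ", ")),
          class = "coreome_format_error")
  }
  if (!"e_pg" %in% names(profiles)) profiles$e_pg <- NA_real_

  passes <- dplyr::mutate(
    profiles, pass = passes_experiment(.data$e_sol, .data$e_mem, .data$e_tl,
                                       criteria))
  per_group <- dplyr::summarise(
    dplyr::group_by(passes, .data$group_id),
    n_pass = sum(.data$pass),
    contaminant_flag = any(!is.na(.data$e_pg)) &&
      all(.data$e_pg[!is.na(.data$e_pg)] < criteria$t_contaminant),
    .groups = "drop")

  if (!is.null(groups)) {
    per_group <- dplyr::left_join(per_group,
                                  groups[, c("group_id", "members")],
                                  by = "group_id")
    per_group$members[is.na(per_group$members)] <-
      per_group$group_id[is.na(per_group$members)]
  } else {
    per_group$members <- per_group$group_id
  }
  prior <- if (is.null(annotations)) character(0) else annotations$prior_exclusions
  per_group$prior_exclusion_flag <- vapply(
    split_accessions(per_group$members),
    function(m) any(m %in% prior), logical(1))

  per_group$status <- dplyr::case_when(
    per_group$n_pass >= criteria$k_required & !per_group$contaminant_flag &
      !per_group$prior_exclusion_flag ~ "core",
    per_group$n_pass < criteria$k_required ~ "fail_experiments",
    per_group$contaminant_flag ~ "excluded_contaminant",
    TRUE ~ "excluded_prior")

  result <- dplyr::arrange(
    per_group[, c("group_id", "members", "n_pass", "contaminant_flag",
                  "prior_exclusion_flag", "status")],
    factor(.data$status, levels = c("core", "fail_experiments",
                                    "excluded_contaminant", "excluded_prior")),
    .data$group_id)
  structure(list(result = result,
                 passes = passes[, c("group_id", "experiment", "pass")],
                 profiles = profiles, criteria = criteria),
            class = "core_call")
}

#' @export
print.core_call <- function(x, ...) {
  counts <- table(factor(x$result$status,
                         levels = c("core", "fail_experiments",
                                    "excluded_contaminant", "excluded_prior")))
  cat(sprintf("Core-proteome call: %d core / %d fail_experiments / %d excluded_contaminant / %d excluded_prior\n",
              counts["core"], counts["fail_experiments"],
              counts["excluded_contaminant"], counts["excluded_prior"]))
  invisible(x)
}

#' Calibrate the contaminant-exclusion threshold from a reference list
#'
#' Finds the highest target/contaminant ratio among groups known to reside
#' in the contaminant organelle, and returns the smallest threshold on the
#' stated granularity that excludes every one of them: the observed maximum
#' is rounded at `margin` granularity, then raised to the next multiple of
#' `step` strictly above it. With the defaults an observed maximum of 3.99
#' calibrates to 4.0 — the "less than 4 is a contaminant" rule.
#'
#' @param profiles Output of [enrichment_ratios()] (needs `e_pg`).
#' @param contaminant_reference Accessions of known contaminant residents.
#' @param margin Rounding granularity of the observed maximum (default 0.01).
#' @param step Threshold granularity (default 1: integer-like thresholds).
#' @param groups Optional [build_groups()] output for member matching.
#' @return A `contaminant_calibration` list: `threshold`, `max_ratio`,
#'   `group_id` (the reference group attaining the maximum), `n_reference`.
#' @export
calibrate_contaminant_threshold <- function(profiles, contaminant_reference,
                                            margin = 0.01, step = 1,
                                            groups = NULL) {
  members <- if (is.null(groups)) {
    setNames(unique(profiles$group_id), unique(profiles$group_id))
  } else {
    setNames(groups$members, groups$group_id)
  }
  is_ref <- vapply(split_accessions(members[unique(profiles$group_id)]),
                   function(m) any(m %in% contaminant_reference), logical(1))
  ref_ids <- unique(profiles$group_id)[is_ref]
  obs <- profiles[profiles$group_id %in% ref_ids & !is.na(profiles$e_pg), ]
  if (any(is.infinite(obs$e_pg))) {
    warn("Reference contaminant(s) with infinite target/contaminant ratio ignored in calibration.")
    obs <- obs[is.finite(obs$e_pg), ]
  }
  if (nrow(obs) == 0) {
    abort("No reference contaminant with a defined contaminant ratio; cannot calibrate.",
          class = "coreome_calibration_error")
  }
  i <- which.max(obs$e_pg)
  max_ratio <- obs$e_pg[i]
  rounded <- round(max_ratio / margin) * margin
  threshold <- step * (floor(rounded / step + 1e-9) + 1)
  structure(list(threshold = threshold, max_ratio = max_ratio,
                 group_id = obs$group_id[i], n_reference = length(ref_ids)),
            class = "contaminant_calibration")
}

#' @export
print.contaminant_calibration <- function(x, ...) {
  cat(sprintf("Contaminant threshold %.2f (max reference ratio %.2f in %s; %d reference group(s))\n",
              x$threshold, x$max_ratio, x$group_id, x$n_reference))
  invisible(x)
}
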