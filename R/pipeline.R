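#' Run the full core-proteome pipeline
#'
#' End-to-end orchestration: read (or accept) the peptide table, build
#' protein groups, compute uniqueness-based relative abundances, average
#' replicates, form per-experiment enrichment ratios, and apply the
#' multi-criteria filter; in parallel, compute TOP3 abundances in the target
#' fraction and the mass contribution of every core group. Precomputed
#' enrichment profiles can be injected via `profiles` (e.g. a published
#' ratio table), in which case the quantification stages are skipped.
#'
#' @param table Peptide quantification tibble (or `NULL` with `path`).
#' @param path Optional file read with [read_peptide_table()].
#' @param profiles Optional precomputed profile tibble
#'   (`group_id`, `experiment`, `e_sol`, `e_mem`, `e_tl`, `e_pg`).
#' @param annotations An [annotation_lists()].
#' @param criteria A [filter_criteria()].
#' @param fraction_set Declared fraction labels (for reading).
#' @param target_fraction,soluble,membrane,total,contaminant Fraction roles.
#' @param min_peptides Minimum unique peptides per quantifiable group.
#' @param convention Mass-contribution convention, see [top3_summary()].
#' @param out_dir If non-`NULL`, reports and a machine-readable run summary
#'   are written there.
#' @return A `core_pipeline` object: list with `groups`, `profiles`, `call`
#'   (a `core_call`), `top3` (a [top3_summary()] over core groups, `NULL`
#'   under profile injection), and `summary` (named status counts).
#' @examples
#' sim <- simulate_dataset(synthetic_config(noise_sigma = 0, response_sigma = 0))
#' fit <- run_core_pipeline(sim$table)
#' fit$summary
#' @export
run_core_pipeline <- function(table = NULL, path = NULL, profiles = NULL,
                              annotations = annotation_lists(),
                              criteria = filter_criteria(),
                              fraction_set = c("LD", "SOL", "MEM", "TL", "PG"),
                              target_fraction = "LD", soluble = "SOL",
                              membrane = "MEM", total = "TL",
                              contaminant = "PG", min_peptides = 2L,
                              convention = "percent_of_averages",
                              out_dir = NULL) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("Pipeline stage '%s' failed: %s", name, conditionMessage(e)),
            class = "coreome_pipeline_error", parent = e)
    })
  }
  groups <- NULL
  top3 <- NULL
  if (is.null(profiles)) {
    if (is.null(table)) {
      if (is.null(path)) {
        abort("Provide `table`, `path`, or `profiles`.",
              class = "coreome_config_error")
      }
      table <- stage("read", read_peptide_table(path, fraction_set, quiet = TRUE))
    }
    groups <- stage("group", build_groups(table, min_peptides))
    rel <- stage("quantify", suppressWarnings(
      relative_abundance(table, groups, "unique_sum")))
    profiles <- stage("enrich", enrichment_ratios(
      rel, target_fraction, soluble, membrane, total, contaminant))
  }
  call <- stage("filter", call_core_proteome(profiles, criteria, annotations,
                                             groups))
  if (!is.null(table) && !is.null(groups)) {
    core_ids <- call$result$group_id[call$result$status == "core"]
    if (length(core_ids)) {
      top3 <- stage("top3", suppressWarnings(top3_summary(
        table, groups[groups$group_id %in% core_ids, , drop = FALSE],
        target_fraction, convention)))
    }
  }
  counts <- table(factor(call$result$status,
                         levels = c("core", "fail_experiments",
                                    "excluded_contaminant", "excluded_prior")))
  out <- structure(list(groups = groups, profiles = profiles, call = call,
                        top3 = top3, summary = c(counts),
                        criteria = criteria),
                   class = "core_pipeline")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    if (!is.null(top3)) {
      write_core_report(call, top3, out_dir)
    } else {
      write_core_report(call, empty_top3_summary(), out_dir)
    }
    run_summary <- c(
      sprintf("coreome_version\t%s", as.character(utils::packageVersion("coreome"))),
      sprintf("config_hash\t%s", rlang::hash(list(criteria, target_fraction,
                                                  min_peptides, convention))),
      sprintf("t_total\t%g", criteria$t_total),
      sprintf("t_soluble\t%g", criteria$t_soluble),
      sprintf("t_membrane\t%g", criteria$t_membrane),
      sprintf("t_contaminant\t%g", criteria$t_contaminant),
      sprintf("k_required\t%d", criteria$k_required),
      sprintf("n_experiments\t%d", criteria$n_experiments),
      sprintf("n_%s\t%d", names(counts), as.integer(counts)))
    writeLines(run_summary, file.path(out_dir, "run_summary.tsv"))
  }
  out
}

empty_top3_summary <- function() {
  out <- tibble::tibble(group_id = character(), members = character(),
                        average = numeric(), mass_contribution = numeric())
  class(out) <- c("top3_summary", class(out))
  out
}

#' @export
print.core_pipeline <- function(x, ...) {
  cat(sprintf("core_pipeline: %s\n",
              paste(sprintf("%d %s", as.integer(x$summary), names(x$summary)),
                    collapse = " / ")))
  invisible(x)
}

#' Rank groups by mass contribution
#'
#' Top-`n` groups of a TOP3 summary by mass contribution, with the running
#' cumulative percentage — e.g. to ask how much of the organelle's protein
#' mass its two most abundant proteins represent.
#'
#' @param top3 A [top3_summary()].
#' @param n How many groups (capped at the number available).
#' @return Tibble `group_id`, `members`, `average`, `mass_contribution`,
#'   `cumulative_pct`.
#' @export
summarize_top_proteins <- function(top3, n = 5L) {
  defined <- dplyr::filter(top3, !is.na(.data$mass_contribution))
  if (nrow(defined) == 0) {
    abort("No group with a defined mass contribution.",
          class = "coreome_input_error")
  }
  ranked <- dplyr::arrange(defined, dplyr::desc(.data$mass_contribution))
  ranked <- utils::head(ranked, n)
  ranked$cumulative_pct <- cumsum(ranked$mass_contribution)
  ranked[, c("group_id", "members", "average", "mass_contribution",
             "cumulative_pct")]
}

#' Fold difference between two groups' average abundances
#'
#' @param top3 A [top3_summary()].
#' @param group_a,group_b Group identifiers; the result is
#'   `average(group_a) / average(group_b)`.
#' @return A single ratio.
#' @export
fold_difference <- function(top3, group_a, group_b) {
  get_avg <- function(g) {
    i <- match(g, top3$group_id)
    if (is.na(i)) abort(sprintf("Group %s not in the summary.", g),
                        class = "coreome_input_error")
    top3$average[i]
  }
  a <- get_avg(group_a)
  b <- get_avg(group_b)
  if (is.na(a)) abort(sprintf("Average of %s is undefined.", group_a),
                      class = "coreome_input_error")
  if (is.na(b) || b == 0) abort(sprintf("Average of %s is undefined or zero.",
                                        group_b),
                                class = "coreome_input_error")
  a / b
}
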