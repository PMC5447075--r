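#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a core-proteome call
#'
#' One row per protein group with its membership, pass count, exclusion
#' flags and final status.
#'
#' @param x A `core_call` from [call_core_proteome()].
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.core_call <- function(x, ...) tibble::as_tibble(x$result)

#' Glance at a core-proteome call
#'
#' @param x A `core_call`.
#' @param ... Unused.
#' @return One-row tibble with status counts and the thresholds applied.
#' @export
glance.core_call <- function(x, ...) {
  counts <- table(factor(x$result$status,
                         levels = c("core", "fail_experiments",
                                    "excluded_contaminant", "excluded_prior")))
  tibble::tibble(
    n_groups = nrow(x$result),
    n_core = as.integer(counts["core"]),
    n_fail_experiments = as.integer(counts["fail_experiments"]),
    n_excluded_contaminant = as.integer(counts["excluded_contaminant"]),
    n_excluded_prior = as.integer(counts["excluded_prior"]),
    t_total = x$criteria$t_total, t_soluble = x$criteria$t_soluble,
    t_membrane = x$criteria$t_membrane, t_contaminant = x$criteria$t_contaminant,
    k_required = x$criteria$k_required,
    n_experiments = x$criteria$n_experiments)
}

#' @export
tidy.core_pipeline <- function(x, ...) tidy(x$call)

#' @export
glance.core_pipeline <- function(x, ...) glance(x$call)

#' Plot the per-experiment enrichment profile of a core-proteome call
#'
#' Ratios of the target fraction over each reference fraction, per group and
#' experiment, on a log scale, with the decision thresholds as dashed lines
#' and points coloured by final status.
#'
#' @param object A `core_call`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.core_call <- function(object, ...) {
  long <- tidyr::pivot_longer(object$profiles,
                              cols = c("e_sol", "e_mem", "e_tl"),
                              names_to = "reference", values_to = "ratio")
  long <- dplyr::left_join(long,
                           object$result[, c("group_id", "status")],
                           by = "group_id")
  thr <- tibble::tibble(
    reference = c("e_sol", "e_mem", "e_tl"),
    threshold = c(object$criteria$t_soluble, object$criteria$t_membrane,
                  object$criteria$t_total))
  ggplot2::ggplot(dplyr::filter(long, is.finite(.data$ratio)),
                  ggplot2::aes(x = factor(.data$experiment), y = .data$ratio,
                               colour = .data$status)) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.7) +
    ggplot2::geom_hline(data = thr,
                        ggplot2::aes(yintercept = .data$threshold),
                        linetype = "dashed") +
    ggplot2::scale_y_log10() +
    ggplot2::facet_wrap(~reference,
                        labeller = ggplot2::as_labeller(
                          c(e_sol = "target / soluble",
                            e_mem = "target / membrane",
                            e_tl = "target / total"))) +
    ggplot2::labs(x = "experiment", y = "enrichment ratio", colour = "status")
}

#' Plot ranked mass contributions of a TOP3 summary
#'
#' Bar chart of each group's percent of the summed average TOP3 abundance,
#' most abundant first.
#'
#' @param object A [top3_summary()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.top3_summary <- function(object, ...) {
  d <- dplyr::filter(tibble::as_tibble(object), !is.na(.data$mass_contribution))
  d$group_id <- stats::reorder(d$group_id, -d$mass_contribution)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$group_id,
                                  y = .data$mass_contribution)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "mass contribution (%)") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}
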