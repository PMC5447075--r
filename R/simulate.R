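#' Protein class specification for the synthetic generator
#'
#' Describes one class of simulated proteins: how many there are, their
#' expected protein-level abundance in every fraction (linear scale), and
#' whether the class is, by construction, resident in the target fraction
#' (`is_true_core`), which downstream recovery tests use as ground truth.
#'
#' @param class_name Label, e.g. `"ld_resident"` or `"soluble_background"`.
#' @param n_proteins Number of proteins in the class.
#' @param fraction_means Named numeric vector mapping every fraction label to
#'   a strictly positive expected abundance.
#' @param is_true_core Logical ground-truth flag for the class.
#' @return A `protein_class_spec` list.
#' @seealso [synthetic_config()], [simulate_dataset()]
#' @export
protein_class_spec <- function(class_name, n_proteins, fraction_means,
                               is_true_core = FALSE) {
  if (!is.character(class_name) || length(class_name) != 1L || !nzchar(class_name)) {
    abort("`class_name` must be a non-empty string.", class = "coreome_config_error")
  }
  if (!is.numeric(n_proteins) || length(n_proteins) != 1L || n_proteins < 1) {
    abort("`n_proteins` must be a positive count.", class = "coreome_config_error")
  }
  if (is.null(names(fraction_means)) || any(!nzchar(names(fraction_means)))) {
    abort("`fraction_means` must be a named vector (one entry per fraction).",
          class = "coreome_config_error")
  }
  if (any(!is.finite(fraction_means)) || any(fraction_means <= 0)) {
    abort("`fraction_means` must be strictly positive.", class = "coreome_config_error")
  }
  structure(
    list(class_name = class_name, n_proteins = as.integer(n_proteins),
         fraction_means = fraction_means, is_true_core = isTRUE(is_true_core)),
    class = "protein_class_spec"
  )
}

#' Default synthetic protein classes
#'
#' Five classes of five proteins each, emulating the composition of a lipid
#' droplet (LD) enrichment experiment: true LD residents (strong LD
#' enrichment over every reference fraction), plastoglobule contaminants
#' (co-purifying with LD but equally abundant in the PG fraction), soluble
#' and membrane background proteins, and plastid-annotated proteins that look
#' LD-enriched but carry a prior non-LD localization and are excluded by
#' annotation rather than by ratio.
#'
#' @param fractions Fraction labels; defaults to the five-fraction design
#'   (LD, soluble, membrane, total leaf, plastoglobule).
#' @return List of [protein_class_spec()] objects (25 proteins in total).
#' @export
default_class_specs <- function(fractions = c("LD", "SOL", "MEM", "TL", "PG")) {
  m <- function(...) setNames(c(...), fractions)
  list(
    protein_class_spec("ld_resident",         5, m(1000,  10,  10,  10,  10), is_true_core = TRUE),
    protein_class_spec("pg_contaminant",      5, m( 200,  20,  20,  30, 200)),
    protein_class_spec("soluble_background",  5, m(  20, 500,  50, 200,  20)),
    protein_class_spec("membrane_background", 5, m(  20,  50, 500, 200,  20)),
    protein_class_spec("plastid_annotated",   5, m( 800,  10,  10,  10,  10))
  )
}

#' Configuration of the synthetic peptide-table generator
#'
#' Assembles and validates every knob of the simulation: the fractionation
#' design (fractions, experiments, technical replicates, which experiments
#' include the plastoglobule fraction), the protein classes, the peptide
#' layer (peptides per protein, peptide-specific response factors, shared
#' peptide sets), the noise model, and left-censoring to nd below a
#' detection limit.
#'
#' @param n_experiments Independent experiments (biological cultures).
#' @param n_replicates Technical replicates per experiment.
#' @param fractions Ordered fraction labels.
#' @param pg_experiments Experiments in which the contaminant (PG) fraction
#'   was purified; by default only the last experiment, mirroring a design
#'   where plastoglobules were prepared from one culture only.
#' @param pg_fraction Label of the contaminant fraction restricted to
#'   `pg_experiments`; ignored when absent from `fractions`.
#' @param class_specs List of [protein_class_spec()]; defaults to
#'   [default_class_specs()].
#' @param peptide_count_range Integer range of peptides per protein.
#' @param response_sigma Log-scale SD of the per-peptide response factor,
#'   drawn once per peptide and reused in every sample (the premise of TOP3
#'   quantification is that peptide response is sample-invariant).
#' @param noise_sigma Log-scale SD of multiplicative measurement noise,
#'   independent per (peptide, sample).
#' @param detection_limit Abundance floor; measurements below it are emitted
#'   as nd.
#' @param shared_peptide_pairs Number of consecutive protein pairs given
#'   identical peptide sets (these should be merged into one group by
#'   [build_groups()]).
#' @param seed Integer seed; fully determines the output.
#' @return A validated `synthetic_config` list.
#' @export
synthetic_config <- function(n_experiments = 3, n_replicates = 3,
                             fractions = c("LD", "SOL", "MEM", "TL", "PG"),
                             pg_experiments = 3, pg_fraction = "PG",
                             class_specs = default_class_specs(fractions),
                             peptide_count_range = c(2L, 12L),
                             response_sigma = 0.3, noise_sigma = 0.2,
                             detection_limit = 1, shared_peptide_pairs = 1,
                             seed = 1) {
  chk <- function(ok, field, msg) {
    if (!ok) abort(sprintf("Invalid `%s`: %s", field, msg),
                   class = "coreome_config_error")
  }
  chk(is.numeric(n_experiments) && n_experiments >= 1, "n_experiments", "must be >= 1")
  chk(is.numeric(n_replicates) && n_replicates >= 1, "n_replicates", "must be >= 1")
  chk(is.character(fractions) && length(fractions) >= 2 && !anyDuplicated(fractions),
      "fractions", "must be >= 2 distinct labels")
  chk(all(pg_experiments %in% seq_len(n_experiments)), "pg_experiments",
      "must be a subset of 1..n_experiments")
  chk(length(class_specs) >= 1 &&
        all(vapply(class_specs, inherits, logical(1), "protein_class_spec")),
      "class_specs", "must be a list of protein_class_spec objects")
  for (cs in class_specs) {
    chk(all(fractions %in% names(cs$fraction_means)), "class_specs",
        sprintf("class '%s' misses a fraction mean", cs$class_name))
  }
  chk(is.numeric(peptide_count_range) && length(peptide_count_range) == 2 &&
        peptide_count_range[1] >= 1 && peptide_count_range[1] <= peptide_count_range[2],
      "peptide_count_range", "must be an increasing positive integer pair")
  chk(is.numeric(response_sigma) && response_sigma >= 0, "response_sigma", "must be >= 0")
  chk(is.numeric(noise_sigma) && noise_sigma >= 0, "noise_sigma", "must be >= 0")
  chk(is.numeric(detection_limit) && detection_limit >= 0, "detection_limit", "must be >= 0")
  n_prot <- sum(vapply(class_specs, function(cs) cs$n_proteins, integer(1)))
  chk(is.numeric(shared_peptide_pairs) && shared_peptide_pairs >= 0 &&
        shared_peptide_pairs <= n_prot %/% 2,
      "shared_peptide_pairs", "must be between 0 and n_proteins/2")
  chk(is.numeric(seed) && length(seed) == 1 && is.finite(seed), "seed",
      "must be a finite integer")
  structure(
    list(n_experiments = as.integer(n_experiments),
         n_replicates = as.integer(n_replicates),
         fractions = fractions,
         pg_experiments = as.integer(pg_experiments),
         pg_fraction = pg_fraction,
         class_specs = class_specs,
         peptide_count_range = as.integer(peptide_count_range),
         response_sigma = response_sigma, noise_sigma = noise_sigma,
         detection_limit = detection_limit,
         shared_peptide_pairs = as.integer(shared_peptide_pairs),
         seed = as.integer(seed)),
    class = "synthetic_config"
  )
}

#' Left-censor an abundance to nd below a detection limit
#'
#' Models the "nd" (not detected) entries of a peptide quantification table:
#' a measurement strictly below the limit is emitted as `NA` (the package's
#' in-memory nd marker); the boundary value is kept.
#'
#' @param abundance Non-negative numeric vector.
#' @param limit Detection limit, `>= 0`; `0` is the identity.
#' @return `abundance` with sub-limit values replaced by `NA`.
#' @examples
#' censor_to_nd(c(5, 10, 4.47e4), 10)
#' @export
censor_to_nd <- function(abundance, limit) {
  if (!is.numeric(limit) || length(limit) != 1L || is.na(limit) || limit < 0) {
    abort("`limit` must be a single value >= 0.", class = "coreome_input_error")
  }
  if (any(abundance < 0, na.rm = TRUE)) {
    abort("`abundance` must be non-negative.", class = "coreome_input_error")
  }
  replace(abundance, !is.na(abundance) & abundance < limit, NA_real_)
}

#' Simulate a peptide-level quantification table with known ground truth
#'
#' Generates one row per (peptide, sample) with
#' `abundance = fraction_mean * response_factor(peptide) * exp(noise)`,
#' left-censored to nd below the detection limit. Peptide response factors
#' are drawn once per peptide and reused across all samples; noise is drawn
#' independently per measurement. Proteins in a shared pair carry an
#' identical peptide set (their peptides map to both accessions and sum both
#' proteins' signal). The contaminant (last) fraction is emitted only for
#' the experiments in `config$pg_experiments`. The same seed reproduces the
#' table exactly.
#'
#' @param config A [synthetic_config()].
#' @return A list with `table` (tibble: `peptide_id`, `accessions`,
#'   `fraction`, `experiment`, `replicate`, `abundance`) and `ground_truth`
#'   (tibble: `accession`, `class_name`, `is_true_core`).
#' @examples
#' sim <- simulate_dataset(synthetic_config(seed = 42))
#' dplyr::count(sim$table, fraction, experiment)
#' @export
simulate_dataset <- function(config) {
  if (!inherits(config, "synthetic_config")) {
    abort("`config` must be built with synthetic_config().",
          class = "coreome_config_error")
  }
  set.seed(config$seed)

  # protein layer
  proteins <- purrr::map_dfr(config$class_specs, function(cs) {
    tibble::tibble(class_name = cs$class_name,
                   is_true_core = cs$is_true_core,
                   within = seq_len(cs$n_proteins),
                   mean_list = list(cs$fraction_means[config$fractions]))
  })
  proteins$accession <- sprintf("SIM%03d", seq_len(nrow(proteins)))

  # peptide layer: counts, then shared pairs (second of a pair reuses the
  # first one's peptides), then sample-invariant response factors
  rng <- config$peptide_count_range
  pool <- seq(rng[1], rng[2])
  n_pep <- pool[sample.int(length(pool), nrow(proteins), replace = TRUE)]
  owner <- rep(seq_len(nrow(proteins)), n_pep)
  pep <- tibble::tibble(
    peptide_id = sprintf("pep%05d", seq_along(owner)),
    owners = as.list(owner)
  )
  if (config$shared_peptide_pairs > 0) {
    for (k in seq_len(config$shared_peptide_pairs)) {
      a <- 2L * k - 1L; b <- 2L * k
      pep <- pep[!vapply(pep$owners, function(o) b %in% o, logical(1)), ]
      pep$owners <- lapply(pep$owners, function(o) if (a %in% o) c(o, b) else o)
    }
  }
  pep$accessions <- vapply(pep$owners, function(o)
    paste(sort(proteins$accession[o]), collapse = ";"), character(1))
  pep$response <- exp(rnorm(nrow(pep), 0, config$response_sigma))

  # per-peptide expected abundance in each fraction = sum over owner proteins
  mean_mat <- do.call(rbind, lapply(pep$owners, function(o) {
    Reduce(`+`, proteins$mean_list[o])
  }))
  colnames(mean_mat) <- config$fractions

  # sample layer
  samples <- tidyr::expand_grid(
    fraction = config$fractions,
    experiment = seq_len(config$n_experiments),
    replicate = seq_len(config$n_replicates)
  )
  if (!is.null(config$pg_fraction) && config$pg_fraction %in% config$fractions) {
    samples <- dplyr::filter(samples, .data$fraction != config$pg_fraction |
                               .data$experiment %in% config$pg_experiments)
  }

  tab <- tidyr::expand_grid(samples,
                            pep_idx = seq_len(nrow(pep)))
  noise <- exp(rnorm(nrow(tab), 0, config$noise_sigma))
  tab$abundance <- mean_mat[cbind(tab$pep_idx, match(tab$fraction, config$fractions))] *
    pep$response[tab$pep_idx] * noise
  tab$abundance <- censor_to_nd(tab$abundance, config$detection_limit)
  tab$peptide_id <- pep$peptide_id[tab$pep_idx]
  tab$accessions <- pep$accessions[tab$pep_idx]

  list(
    table = tibble::as_tibble(tab[, c("peptide_id", "accessions", "fraction",
                                      "experiment", "replicate", "abundance")]),
    ground_truth = tibble::tibble(accession = proteins$accession,
                                  class_name = proteins$class_name,
                                  is_true_core = proteins$is_true_core)
  )
}

#' Score core-proteome recovery against simulation ground truth
#'
#' Compares the accessions of groups called `core` with the `is_true_core`
#' flag of the generator, at the accession level.
#'
#' @param result A [call_core_proteome()] result (or its tidy tibble).
#' @param ground_truth Tibble with `accession` and `is_true_core`.
#' @return One-row tibble with `recall`, `precision`, `n_true`, `n_called`.
#' @export
score_recovery <- function(result, ground_truth) {
  res <- if (inherits(result, "core_call")) result$result else result
  called <- unlist(split_accessions(res$members[res$status == "core"]))
  truth <- ground_truth$accession[ground_truth$is_true_core]
  tibble::tibble(
    recall = if (length(truth)) mean(truth %in% called) else NA_real_,
    precision = if (length(called)) mean(called %in% truth) else NA_real_,
    n_true = length(truth),
    n_called = length(called)
  )
}
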