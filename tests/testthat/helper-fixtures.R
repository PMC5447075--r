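# Build a long peptide table from compact per-peptide specs.
# peptides: named list accession-string -> character vector of peptide ids
# abundance: function(peptide_id, fraction, experiment, replicate) -> value
toy_table <- function(peptides, samples, abundance) {
  pep <- tibble::tibble(
    accessions = rep(names(peptides), lengths(peptides)),
    peptide_id = unlist(peptides, use.names = FALSE))
  tab <- tidyr::expand_grid(samples, pep)
  tab$abundance <- mapply(abundance, tab$peptide_id, tab$fraction,
                          tab$experiment, tab$replicate)
  tab[, c("peptide_id", "accessions", "fraction", "experiment", "replicate",
          "abundance")]
}

default_samples <- function(fractions = c("LD", "SOL", "MEM", "TL"),
                            experiments = 1:3, replicates = 1:3) {
  tidyr::expand_grid(fraction = fractions, experiment = experiments,
                     replicate = replicates)
}

# Two-protein configuration whose per-fraction totals are equal, so that
# relative normalization leaves the test protein's enrichment ratio exactly
# at the ratio of its fraction means (here 50x over every reference).
balanced_50x_config <- function(seed = 1, noise_sigma = 0,
                                fractions = c("LD", "SOL", "MEM", "TL", "PG")) {
  m <- function(...) stats::setNames(c(...), fractions)
  synthetic_config(
    fractions = fractions,
    class_specs = list(
      protein_class_spec("ld_resident", 1, m(50, 1, 1, 1, 1),
                         is_true_core = TRUE),
      protein_class_spec("balance", 1, m(50, 99, 99, 99, 99))),
    peptide_count_range = c(2L, 2L),
    response_sigma = 0, noise_sigma = noise_sigma,
    detection_limit = 0, shared_peptide_pairs = 0, seed = seed)
}

# Exhaustive identical-peptide-set grouping oracle (independent of
# build_groups): pairwise set comparison over a peptide->accession map.
oracle_groups <- function(ev) {
  accs <- sort(unique(ev$accession))
  sets <- lapply(accs, function(a) sort(unique(ev$peptide_id[ev$accession == a])))
  names(sets) <- accs
  assigned <- rep(NA_integer_, length(accs))
  g <- 0L
  for (i in seq_along(accs)) {
    if (!is.na(assigned[i])) next
    g <- g + 1L
    assigned[i] <- g
    if (i < length(accs)) {
      for (j in seq(i + 1L, length(accs))) {
        if (is.na(assigned[j]) && identical(sets[[i]], sets[[j]])) assigned[j] <- g
      }
    }
  }
  membership <- split(accs, assigned)
  acc2grp <- stats::setNames(rep(seq_along(membership), lengths(membership)),
                             unlist(membership))
  peps <- sort(unique(ev$peptide_id))
  unique_pep <- vapply(peps, function(p) {
    length(unique(acc2grp[unique(ev$accession[ev$peptide_id == p])])) == 1L
  }, logical(1))
  list(membership = unname(lapply(membership, sort)),
       unique_peptides = peps[unique_pep])
}

# Profile tibble builder for filter-level tests (injection format).
profile_row <- function(group_id, experiment, e_sol, e_mem, e_tl, e_pg = NA_real_) {
  tibble::tibble(group_id = group_id, experiment = experiment,
                 e_sol = e_sol, e_mem = e_mem, e_tl = e_tl, e_pg = e_pg)
}

synthetic_prior_annotations <- function(ground_truth) {
  annotation_lists(
    prior_exclusions =
      ground_truth$accession[ground_truth$class_name == "plastid_annotated"])
}
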