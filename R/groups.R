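#' Group proteins by identical peptide evidence
#'
#' Accessions identified by exactly the same set of peptides (over the union
#' of all samples) cannot be distinguished by the data and are merged into
#' one protein group, identified by its lexicographically smallest member
#' accession. Only identical sets are merged — no subset or parsimony
#' collapsing. A peptide is *unique* to a group when every accession it maps
#' to belongs to that group; unique peptides are the evidence base for
#' between-sample quantification, and a group is `quantifiable` when it has
#' at least `min_peptides` of them.
#'
#' @param table Peptide quantification table (long tibble with `peptide_id`
#'   and semicolon-joined `accessions`).
#' @param min_peptides Minimum number of unique peptides for a group to be
#'   quantifiable (default 2).
#' @return Tibble sorted by `group_id` with columns `group_id`, `members`
#'   (semicolon-joined), `peptides` and `unique_peptides` (list-columns),
#'   `n_peptides`, `n_unique`, `quantifiable`.
#' @examples
#' tab <- tibble::tibble(
#'   peptide_id = c("p1", "p2", "p3", "p2"),
#'   accessions = c("A", "A;B", "A", "A;B"),
#'   fraction = "LD", experiment = 1L, replicate = c(1L, 1L, 1L, 2L),
#'   abundance = c(10, 20, 30, 25))
#' build_groups(tab)
#' @export
build_groups <- function(table, min_peptides = 2L) {
  if (nrow(table) == 0) {
    return(tibble::tibble(group_id = character(), members = character(),
                          peptides = list(), unique_peptides = list(),
                          n_peptides = integer(), n_unique = integer(),
                          quantifiable = logical()))
  }
  # peptide -> accession incidence over the union of all samples
  ev <- dplyr::distinct(
    tidyr::unnest(
      dplyr::mutate(dplyr::distinct(table, .data$peptide_id, .data$accessions),
                    accession = split_accessions(.data$accessions)),
      "accession"),
    .data$peptide_id, .data$accession)

  by_acc <- dplyr::summarise(dplyr::group_by(ev, .data$accession),
                             pepset = list(sort(unique(.data$peptide_id))),
                             .groups = "drop")
  by_acc$key <- vapply(by_acc$pepset, paste, character(1), collapse = "\r")

  groups <- dplyr::summarise(
    dplyr::group_by(by_acc, .data$key),
    group_id = min(.data$accession),
    members = paste(sort(.data$accession), collapse = ";"),
    peptides = .data$pepset[1],
    .groups = "drop")

  # a peptide is unique iff all its accessions fall in a single group
  acc2grp <- setNames(rep(groups$group_id, lengths(split_accessions(groups$members))),
                      unlist(split_accessions(groups$members)))
  pep_groups <- dplyr::summarise(
    dplyr::group_by(ev, .data$peptide_id),
    n_groups = dplyr::n_distinct(acc2grp[.data$accession]),
    .groups = "drop")
  unique_peps <- pep_groups$peptide_id[pep_groups$n_groups == 1L]

  groups$unique_peptides <- lapply(groups$peptides, intersect, y = unique_peps)
  groups$n_peptides <- lengths(groups$peptides)
  groups$n_unique <- lengths(groups$unique_peptides)
  groups$quantifiable <- groups$n_unique >= min_peptides
  dplyr::arrange(
    dplyr::select(groups, "group_id", "members", "peptides", "unique_peptides",
                  "n_peptides", "n_unique", "quantifiable"),
    .data$group_id)
}
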