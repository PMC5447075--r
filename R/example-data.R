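#' Published aging-leaf lipid-droplet study tables
#'
#' Two worked-example tables from a label-free quantitative study of the
#' *Arabidopsis thaliana* aging-leaf lipid-droplet (LD) proteome, shipped as
#' plain TSV under `inst/extdata` and loaded here into the package's native
#' shapes:
#'
#' * `ld_study_ratios()` — the 28 core-proteome groups with their printed
#'   per-experiment enrichment ratios (LD over soluble, membrane, and
#'   total-leaf fractions in each of three independent experiments, plus the
#'   LD/plastoglobule ratio from the single experiment with a plastoglobule
#'   preparation). Returned as an enrichment-profile tibble (`group_id`,
#'   `experiment`, `e_sol`, `e_mem`, `e_tl`, `e_pg`) ready for
#'   [call_core_proteome()]; the LD/plastoglobule column is attached to
#'   experiment 3, `nd` entries are `NA`.
#' * `ld_study_top3()` — the same groups' per-experiment TOP3 abundances in
#'   the LD fraction with the printed nd-aware averages and mass
#'   contributions (`top3_exp1..3`, `average_printed`, `mass_pct_printed`).
#'
#' @return A tibble; `ld_study_ratios(long = FALSE)` returns the raw wide
#'   table including protein names and group membership.
#' @param long Return the long profile form (default) or the raw wide table.
#' @examples
#' call <- call_core_proteome(ld_study_ratios())
#' glance(call)
#' @name ld_study
NULL

#' @rdname ld_study
#' @export
ld_study_ratios <- function(long = TRUE) {
  path <- system.file("extdata", "aging_leaf_ld_ratios.tsv", package = "coreome")
  wide <- readr::read_tsv(path, col_types = readr::cols(
    group_id = "c", members = "c", protein_name = "c", .default = "c"),
    progress = FALSE, na = "nd")
  num_cols <- setdiff(names(wide), c("group_id", "members", "protein_name"))
  wide[num_cols] <- lapply(wide[num_cols], as.numeric)
  if (!long) return(wide)
  purrr::map_dfr(1:3, function(e) {
    tibble::tibble(
      group_id = wide$group_id,
      experiment = e,
      e_sol = wide[[sprintf("e%d_sol", e)]],
      e_mem = wide[[sprintf("e%d_mem", e)]],
      e_tl = wide[[sprintf("e%d_tl", e)]],
      e_pg = if (e == 3) wide$ld_pg else NA_real_)
  })
}

#' @rdname ld_study
#' @export
ld_study_top3 <- function() {
  path <- system.file("extdata", "aging_leaf_ld_top3.tsv", package = "coreome")
  readr::read_tsv(path, col_types = readr::cols(
    group_id = "c", members = "c", protein_name = "c", .default = "d"),
    progress = FALSE, na = "nd")
}
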