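---
title: "Calling an organelle core proteome from label-free peptide quantification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling an organelle core proteome from label-free peptide quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coreome)
library(dplyr)
```

## The problem

Subcellular fractions are never pure. When an organelle such as the plant
lipid droplet (LD) is floated out of a leaf homogenate, the preparation
carries along abundant soluble proteins, membrane fragments, and — most
troublesome — plastoglobules (PG), plastid-internal lipoprotein particles of
nearly the same density. A protein list from a single LD fraction therefore
says little about residency. The remedy implemented here is comparative:
quantify every protein in the target fraction *and* in reference fractions
prepared from the same material (soluble, membrane, total extract,
contaminant organelle), and call a protein a *core* component only when it
is reproducibly enriched in the target over every reference.

`coreome` implements that procedure end to end on peptide-level label-free
quantification tables — the long-format export of peak-processing software,
one normalized abundance per (peptide, sample) — together with a synthetic
generator of such tables so that every stage can be exercised against known
ground truth.

## From peptides to protein groups

Peptides are assigned to proteins by the identification search; several
accessions frequently share their entire peptide evidence (gene families,
indistinguishable isoforms). Accessions with *identical* peptide sets over
the union of all samples are merged into one group and counted once
(`build_groups()`). Only identical sets are merged: subset relations and
parsimony arguments are deliberately not applied, because the data cannot
distinguish members of an identical-set group but can, in principle,
distinguish a subset protein.

A peptide is **unique** when every accession it maps to lies in a single
group. Unique peptides are the basis of all between-sample quantification;
a group is quantifiable when it has at least `min_peptides = 2` of them.
The floor is applied to *unique* peptides: shared peptides carry signal
from several groups and cannot support a per-group quantity. (Published
descriptions of the minimum-two-peptides rule do not always say which count
is meant; reports therefore carry `n_peptides` and `n_unique` side by
side.)

## Two abundance estimators

Two estimators serve two different questions:

* **`unique_sum`** — the sum of a group's measured unique peptides in a
  sample. Used for *between-sample* comparison of the same protein, where
  peptide response factors cancel.
* **`top3`** — the sum of the three most abundant unique peptides (Hi-3).
  The average intensity of a protein's best-responding peptides is
  approximately proportional to molar amount, so `top3` supports
  *within-sample* comparison of different proteins and mass-contribution
  percentages. With fewer than three measured peptides the estimator sums
  what exists and flags `n_used < 3` rather than dropping the protein,
  because two-peptide proteins are legitimately quantifiable under the
  evidence floor.

TOP3 is restricted to unique peptides: a shared peptide would count the
same ion current toward several groups and the mass contributions would no
longer sum to 100%.

Not-detected measurements (`nd`) travel as `NA` from the parsers through
every average: means are taken over detected values only, and a quantity
whose inputs are all `nd` stays `nd`. Zero-imputation is never used — a
protein below the detection limit in one replicate is missing, not absent.

## Relative normalized abundance and enrichment ratios

Raw per-sample abundances are not comparable between samples of very
different total protein signal. Each group's abundance is therefore divided
by the summed abundance of **all** measured peptides in that sample
(shared, ungrouped and sub-floor peptides included), giving its relative
normalized abundance `r` — the group's share of the sample's peptide
signal. `r` is invariant under per-sample rescaling, which is exactly the
property the downstream ratios need.

For each experiment, `r` is averaged over the technical replicates within
each fraction (nd excluded), and enrichment ratios are formed per group:

    E_sol = r̄(target) / r̄(soluble)
    E_mem = r̄(target) / r̄(membrane)
    E_tl  = r̄(target) / r̄(total extract)
    E_pg  = r̄(target) / r̄(contaminant)   [only in experiments with such a sample]

Averaging first and taking the ratio second is the default
(`ratio_of_averages = TRUE`); the per-replicate-ratio-then-average variant
is exposed because both orders appear in practice and they differ under
noise. At zero noise the two coincide, which the test suite verifies.

Degenerate cases are resolved as follows and logged: a ratio whose target
average is nd is nd; a measured target over a reference that is nd or
exactly zero is the infinite marker (`Inf`). Absence from a reference
fraction is maximal enrichment evidence, so `Inf` passes every threshold;
nd fails every threshold.

## The decision rule

Per experiment, a group passes when

* `E_tl` **strictly exceeds** `t_total` (default 6), and
* `E_sol` and `E_mem` are **at least** `t_soluble`/`t_membrane`
  (default 1.5).

The asymmetry in strictness is intentional and mirrors the wording of the
published criteria this rule reproduces ("superior to 6" versus "inferior
to 1.5 were discarded"): a membrane ratio of exactly 1.5 is kept, a
total-extract ratio of exactly 6 is not. The total-extract threshold is
deliberately low in absolute terms — whole-cell protein dwarfs organelle
protein, so genuine residents can score modest `E_tl` while still clearing
abundant cytosolic and photosynthetic proteins.

A group is called **core** when it passes in at least `k_required = 2` of
`n_experiments = 3` independent experiments and neither exclusion applies:

* **Contaminant exclusion** — if *every* available `E_pg` is below
  `t_contaminant` (default 4) the group is considered a contaminant-organelle
  resident rather than a target resident. A missing `E_pg` (no contaminant
  sample in any experiment where the group was seen) never excludes:
  absence of evidence is not evidence of contamination.
* **Prior exclusion** — groups on a user-supplied list of accessions with a
  previously characterized non-target localization.

Experiments where the group is entirely nd count as *failed*, not as
missing, toward k-of-n; a protein detected in only two experiments can
still reach k = 2 by passing both. Non-core statuses are reported with the
precedence `fail_experiments` → `excluded_contaminant` → `excluded_prior`,
chosen so that ratio evidence is reported before annotation evidence; the
core condition itself is independent of the precedence.

The contaminant threshold can also be *calibrated* from data
(`calibrate_contaminant_threshold()`): given reference accessions known to
reside in the contaminant organelle, the threshold is the smallest value on
a unit step strictly above their highest observed `E_pg` (rounded at 0.01
granularity). A reference maximum of 3.99 calibrates to 4.0 — every known
contaminant is excluded with the least collateral damage.

## Mass contributions

For the proteins called core, per-experiment TOP3 values in the target
fraction are replicate-averaged, experiment-averaged (nd excluded), and
expressed as percentages of the summed averages. The defined percentages
sum to exactly 100 before rounding. Whether such a percentage should be
computed from averaged abundances (default, `percent_of_averages`) or as an
average of per-sample percentages (`average_of_percents`) is not uniquely
determined by common practice; both are implemented, and recomputation of
published tables with either convention agrees only approximately with
printed percentage columns (printed averages are themselves rounded), so
neither is asserted to be "the" published convention.

## The synthetic generator

`simulate_dataset()` emulates the fractionation design the filter assumes:
five fractions (target LD, soluble, membrane, total extract, contaminant
PG), three independent experiments of three technical replicates, with the
contaminant fraction present in a single experiment — mirroring designs
where the contaminant organelle is purified only once. Peptide measurements
are generated as

    abundance = fraction_mean(protein) x response(peptide) x exp(noise)

* **Response factors** are log-normal (`response_sigma`, default 0.3),
  drawn once per peptide and reused in every sample — the sample-invariance
  premise that makes TOP3 work.
* **Noise** is multiplicative log-normal per measurement (`noise_sigma`,
  default 0.2), the conventional model for label-free intensity data.
* **Left-censoring**: values below `detection_limit` (default 1, against
  class means of 10–1000) are emitted as `nd`, never as zero.
* **Shared evidence**: `shared_peptide_pairs` protein pairs are given
  identical peptide sets, whose peptides sum both proteins' signal — the
  case `build_groups()` must merge.

The default population is 25 proteins in five classes of five: true LD
residents (100x enrichment over every reference at the fraction-mean
level), PG contaminants (equal LD and PG means, so their LD/PG ratio is ~1),
soluble and membrane background, and "plastid-annotated" proteins that pass
every ratio and are excluded only by the prior-annotation list. Because
enrichment is computed on *relative* abundances, realized ratios are the
mean ratios rescaled by total-signal ratios between fractions (e.g. the
100x residents realize `E_tl` near 20 under the default population); class
means were chosen so every class sits far from its decision boundary at the
default noise level, and they are fixed — they are the test conditions, not
tuning knobs.

What the generator does **not** emulate: identification error,
chromatographic alignment artifacts, intensity-dependent (heteroscedastic)
noise, ragged peptide detectability across samples, or correlated
contamination structure. Perfect recovery on synthetic data therefore
demonstrates that the pipeline's arithmetic and decision logic are correct
under the model's assumptions, not that real fractionation data will be
this clean.

A note on one construction used in the tests: with a *single* simulated
protein, relative abundance is identically 1 in every sample and all
enrichment ratios collapse to 1, so exact-ratio checks pair the protein of
interest with a complementary "balance" protein making per-fraction totals
equal — then the realized ratios equal the specified mean ratios exactly at
zero noise (the 50x design used in the tests and described below).

## Worked example: the published ratio table

The package ships the printed enrichment-ratio and TOP3 tables of an aging
*Arabidopsis* leaf LD study as plain-text fixtures. The ratio table enters
the pipeline at the profile-injection point, downstream of quantification:

```{r fixture}
call <- call_core_proteome(ld_study_ratios(), filter_criteria())
glance(call)

t3 <- ld_study_top3()
summary_tbl <- tibble::tibble(group_id = t3$group_id, members = t3$members,
                              average = t3$average_printed,
                              mass_contribution = t3$mass_pct_printed)
summarize_top_proteins(summary_tbl, 2)
fold_difference(summary_tbl, "AT2G33380", "AT3G01420")
```

All 28 groups are recovered as core; the two most abundant proteins (the
caleosin CLO3 and the small rubber particle protein SRPP1/LDAP1) together
carry about 74% of the LD protein mass, and CLO3 exceeds its enzymatic
partner α-DOX1 roughly 189-fold.

## Synthetic round trip

```{r roundtrip}
sim <- simulate_dataset(synthetic_config(seed = 42))
ann <- annotation_lists(
  prior_exclusions =
    sim$ground_truth$accession[sim$ground_truth$class_name == "plastid_annotated"])
fit <- run_core_pipeline(sim$table, annotations = ann)
fit$summary
score_recovery(fit$call, sim$ground_truth)
```

## Problem sizes, tolerances, numerical choices

* The test suite uses 20 simulated datasets of 25 proteins (roughly 5,000 -
  7,000 table rows each) for the recovery checks, 100 small single-protein
  datasets for the Monte-Carlo mean-recovery check, and 20-25 random
  instances for each property suite (grouping oracle, threshold
  monotonicity, calibration dominance, TOP3 monotonicity); these sizes give
  the properties room to fail while keeping the default run brisk.
* Exactness: zero-noise checks assert exact equality; mass-contribution
  closure asserts 100 within 1e-9; printed-value checks assert agreement at
  the tables' printed precision (3 significant figures).
* Ties and boundaries: `censor_to_nd` keeps a value equal to the detection
  limit; `passes_experiment` keeps ratios equal to the soluble/membrane
  thresholds and rejects a total ratio equal to its threshold; group
  identifiers are the lexicographically smallest member accession, and all
  outputs are deterministically ordered (status, then group id).

## Limitations

* The filter is purely threshold-based, as in the procedure it reproduces:
  no error model, p-values, or FDR accompany a core call. Thresholds encode
  the biology of one fractionation design and should be re-examined for
  others (`filter_criteria()` makes them explicit).
* Upstream normalization between runs is assumed done by the peak-processing
  software; the package normalizes within samples only.
* The identical-set grouping is conservative; proteins distinguished only
  by subset peptides remain separate groups whose shared peptides are
  unusable for quantification.
* The contaminant calibration presumes the reference list is itself
  trustworthy and quantified in the contaminant fraction.
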