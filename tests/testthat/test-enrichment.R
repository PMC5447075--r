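test_that("enrichment ratios are replicate-averaged target over reference, with Inf for absent references", {
  samples <- default_samples(c("LD", "SOL", "MEM", "TL"), 1, 1:3)
  vals <- function(p, f, e, r) {
    c(LD = 200, SOL = 40, MEM = 20, TL = 20)[f] * c(p1 = 1, p2 = 2)[p]
  }
  tab <- toy_table(list(A = c("p1", "p2"), B = c("p3", "p4")), samples,
                   function(p, f, e, r) {
                     if (p %in% c("p3", "p4")) 100 else vals(p, f, e, r)
                   })
  g <- build_groups(tab)
  rel <- relative_abundance(tab, g)
  prof <- enrichment_ratios(rel)
  a <- prof[prof$group_id == "A", ]
  # relative shares: LD 600/800, SOL 120/320, MEM 60/260, TL 60/260
  expect_equal(a$e_sol, (600 / 800) / (120 / 320))
  expect_equal(a$e_tl, (600 / 800) / (60 / 260))
  expect_true(is.na(a$e_pg))  # no PG samples in the design

  # reference fraction missing entirely for the group -> infinite marker
  tab2 <- toy_table(list(A = c("p1", "p2"), B = c("p3", "p4")), samples,
                    function(p, f, e, r) {
                      if (p %in% c("p1", "p2") && f == "SOL") NA
                      else if (p %in% c("p3", "p4")) 100
                      else vals(p, f, e, r)
                    })
  prof2 <- enrichment_ratios(relative_abundance(tab2, build_groups(tab2)))
  expect_identical(prof2$e_sol[prof2$group_id == "A"], Inf)

  # target nd -> all ratios nd for that experiment
  tab3 <- toy_table(list(A = c("p1", "p2"), B = c("p3", "p4")), samples,
                    function(p, f, e, r) {
                      if (p %in% c("p1", "p2") && f == "LD") NA
                      else if (p %in% c("p3", "p4")) 100
                      else vals(p, f, e, r)
                    })
  prof3 <- enrichment_ratios(relative_abundance(tab3, build_groups(tab3)))
  expect_true(all(is.na(prof3[prof3$group_id == "A", c("e_sol", "e_mem", "e_tl")])))
})

test_that("zero-noise 50x balanced design yields ratios of exactly 50 and a core call", {
  sim <- simulate_dataset(balanced_50x_config())
  g <- build_groups(sim$table)
  prof <- enrichment_ratios(relative_abundance(sim$table, g))
  ld <- prof[prof$group_id == sim$ground_truth$accession[1], ]
  expect_equal(ld$e_sol, rep(50, 3))
  expect_equal(ld$e_mem, rep(50, 3))
  expect_equal(ld$e_tl, rep(50, 3))
  expect_equal(ld$e_pg[3], 50)
  call <- call_core_proteome(prof, filter_criteria())
  expect_identical(call$result$status[call$result$group_id == ld$group_id[1]],
                   "core")
})

test_that("per-experiment pass rule follows published strictness conventions", {
  crit <- filter_criteria()
  # total-extract ratio of 3.1 is below the strict > 6 rule
  expect_false(passes_experiment(2.8, 40.2, 3.1, crit))
  # a membrane ratio equal to 1.5 is kept (only strictly smaller is discarded)
  expect_true(passes_experiment(12.0, 1.5, 8.3, crit))
  expect_false(passes_experiment(0.5, 0.2, 0.7, crit))
  # nd fails, Inf passes
  expect_false(passes_experiment(NA, 2, 10, crit))
  expect_true(passes_experiment(Inf, Inf, Inf, crit))
})

test_that("core call applies the k-of-n rule, contaminant and prior exclusions", {
  crit <- filter_criteria()
  prof <- dplyr::bind_rows(
    # pass pattern (F,T,T) with contaminant ratio 4.4 -> core
    profile_row("ADOX1", 1:3, e_sol = c(2.8, 19.8, 3.2),
                e_mem = c(40.2, 21.5, 3.3), e_tl = c(3.1, 21.7, 6.6),
                e_pg = c(NA, NA, 4.4)),
    # all experiments pass but every contaminant ratio < 4 -> excluded
    profile_row("NEARPG", 1:3, e_sol = 20, e_mem = 10, e_tl = 30,
                e_pg = c(NA, NA, 3.99)),
    # detected in only 2 experiments can still reach k = 2
    profile_row("TWOEXP", 1:3, e_sol = c(NA, 10, 10), e_mem = c(NA, 5, 5),
                e_tl = c(NA, 20, 20), e_pg = NA_real_),
    # passes only once -> fail_experiments
    profile_row("ONEPASS", 1:3, e_sol = c(10, 1, 1), e_mem = c(10, 1, 1),
                e_tl = c(20, 1, 1), e_pg = NA_real_),
    # plastid-annotated passing everything -> excluded by prior annotation
    profile_row("PLASTID", 1:3, e_sol = 50, e_mem = 50, e_tl = 50,
                e_pg = c(NA, NA, 10)))
  ann <- annotation_lists(prior_exclusions = "PLASTID")
  call <- call_core_proteome(prof, crit, ann)
  status <- stats::setNames(call$result$status, call$result$group_id)
  expect_identical(status[["ADOX1"]], "core")
  expect_identical(status[["NEARPG"]], "excluded_contaminant")
  expect_identical(status[["TWOEXP"]], "core")
  expect_identical(status[["ONEPASS"]], "fail_experiments")
  expect_identical(status[["PLASTID"]], "excluded_prior")
  expect_equal(call$result$n_pass[call$result$group_id == "ADOX1"], 2)
})

test_that("raising thresholds never adds a core member; lowering never removes one", {
  set.seed(99)
  prof <- profile_row(sprintf("G%02d", 1:40),
                      experiment = 1L,
                      e_sol = stats::runif(40, 0, 30),
                      e_mem = stats::runif(40, 0, 30),
                      e_tl = stats::runif(40, 0, 30),
                      e_pg = stats::runif(40, 0, 10))
  prof <- dplyr::bind_rows(prof, dplyr::mutate(prof, experiment = 2L,
                                               e_tl = e_tl * 1.3))
  core_set <- function(crit) {
    r <- call_core_proteome(prof, crit)$result
    r$group_id[r$status == "core"]
  }
  base <- core_set(filter_criteria(k_required = 1, n_experiments = 2))
  harder <- core_set(filter_criteria(t_total = 9, t_soluble = 2.5,
                                     t_membrane = 2.5, t_contaminant = 6,
                                     k_required = 1, n_experiments = 2))
  easier <- core_set(filter_criteria(t_total = 3, t_soluble = 1,
                                     t_membrane = 1, t_contaminant = 2,
                                     k_required = 1, n_experiments = 2))
  expect_true(all(harder %in% base))
  expect_true(all(base %in% easier))
})

test_that("contaminant threshold calibrates to the next step above the reference maximum", {
  prof <- profile_row(c("R1", "R2", "R3"), 1L, e_sol = 1, e_mem = 1, e_tl = 1,
                      e_pg = c(1.2, 3.99, 0.5))
  cal <- calibrate_contaminant_threshold(prof, c("R1", "R2", "R3"))
  expect_equal(cal$threshold, 4.0)
  expect_equal(cal$max_ratio, 3.99)
  expect_identical(cal$group_id, "R2")

  zero <- profile_row("R1", 1L, 1, 1, 1, e_pg = 0)
  expect_equal(calibrate_contaminant_threshold(zero, "R1")$threshold, 1.0)

  none <- profile_row("R1", 1L, 1, 1, 1, e_pg = NA_real_)
  expect_error(calibrate_contaminant_threshold(none, "R1"),
               class = "coreome_calibration_error")
})

test_that("the calibrated threshold dominates every reference ratio", {
  for (s in 1:25) {
    set.seed(s)
    n <- sample(2:10, 1)
    prof <- profile_row(sprintf("R%d", 1:n), 1L, 1, 1, 1,
                        e_pg = stats::runif(n, 0, 12))
    cal <- calibrate_contaminant_threshold(prof, sprintf("R%d", 1:n))
    expect_true(all(prof$e_pg < cal$threshold))
    # every reference is excluded by a call using the calibrated threshold
    prof_pass <- dplyr::mutate(prof, e_sol = 100, e_mem = 100, e_tl = 100)
    crit <- filter_criteria(t_contaminant = cal$threshold, k_required = 1,
                            n_experiments = 1)
    res <- call_core_proteome(prof_pass, crit)$result
    expect_true(all(res$status == "excluded_contaminant"))
  }
})

test_that("enrichment ratios are invariant under per-sample rescaling of raw abundances", {
  sim <- simulate_dataset(synthetic_config(seed = 8))
  g <- build_groups(sim$table)
  prof <- enrichment_ratios(suppressWarnings(relative_abundance(sim$table, g)))
  scaled <- dplyr::group_by(sim$table, fraction, experiment, replicate)
  scaled <- dplyr::ungroup(dplyr::mutate(scaled,
    abundance = abundance * stats::runif(1, 0.1, 10)))
  prof2 <- enrichment_ratios(suppressWarnings(relative_abundance(scaled, g)))
  expect_equal(prof2, prof)
})

test_that("ratio-then-average variant agrees at zero noise and differs under noise", {
  sim0 <- simulate_dataset(balanced_50x_config())
  g0 <- build_groups(sim0$table)
  rel0 <- relative_abundance(sim0$table, g0)
  expect_equal(enrichment_ratios(rel0, ratio_of_averages = FALSE),
               enrichment_ratios(rel0))

  simn <- simulate_dataset(balanced_50x_config(seed = 4, noise_sigma = 0.3))
  gn <- build_groups(simn$table)
  reln <- relative_abundance(simn$table, gn)
  expect_false(isTRUE(all.equal(enrichment_ratios(reln, ratio_of_averages = FALSE),
                                enrichment_ratios(reln))))
})
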