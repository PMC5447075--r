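one_sample <- tidyr::expand_grid(fraction = "LD", experiment = 1L, replicate = 1L)

abund_from <- function(values) {
  function(p, ...) unname(values[p])
}

test_that("TOP3 sums the three largest unique peptides; fewer than 3 are summed and flagged", {
  tab <- toy_table(list(A = c("p1", "p2", "p3", "p4")), one_sample,
                   abund_from(c(p1 = 10, p2 = 20, p3 = 30, p4 = 5)))
  g <- build_groups(tab)
  mat <- abundance_matrix(tab, g, "top3")
  expect_equal(mat$abundance, 60)
  expect_equal(mat$n_used, 3L)

  tab2 <- toy_table(list(A = c("p1", "p2")), one_sample,
                    abund_from(c(p1 = 10, p2 = 20)))
  mat2 <- abundance_matrix(tab2, build_groups(tab2), "top3")
  expect_equal(mat2$abundance, 30)
  expect_lt(mat2$n_used, 3L)
})

test_that("unique_sum equals top3 when at most 3 peptides are measured, exceeds it beyond", {
  tab3 <- toy_table(list(A = c("p1", "p2", "p3")), one_sample,
                    abund_from(c(p1 = 10, p2 = 20, p3 = 30)))
  g3 <- build_groups(tab3)
  expect_equal(abundance_matrix(tab3, g3, "unique_sum")$abundance,
               abundance_matrix(tab3, g3, "top3")$abundance)

  for (s in 1:10) {
    set.seed(s)
    n <- sample(4:9, 1)
    vals <- stats::setNames(stats::runif(n, 1, 100), sprintf("p%d", 1:n))
    tab <- toy_table(list(A = names(vals)), one_sample, abund_from(vals))
    g <- build_groups(tab)
    us <- abundance_matrix(tab, g, "unique_sum")$abundance
    t3 <- abundance_matrix(tab, g, "top3")$abundance
    expect_gt(us, t3)
    expect_equal(t3, sum(sort(vals, decreasing = TRUE)[1:3]))
  }
})

test_that("TOP3 is monotone in any contributing peptide abundance", {
  set.seed(42)
  for (i in 1:20) {
    n <- sample(2:6, 1)
    vals <- stats::setNames(stats::runif(n, 1, 100), sprintf("p%d", 1:n))
    tab <- toy_table(list(A = names(vals)), one_sample, abund_from(vals))
    g <- build_groups(tab)
    base <- abundance_matrix(tab, g, "top3")$abundance
    bump <- sample(names(vals), 1)
    vals2 <- vals
    vals2[bump] <- vals2[bump] + stats::runif(1, 0, 50)
    tab2 <- toy_table(list(A = names(vals2)), one_sample, abund_from(vals2))
    expect_gte(abundance_matrix(tab2, g, "top3")$abundance, base)
  }
})

test_that("a group with no measured unique peptide is nd, and non-quantifiable groups are skipped", {
  tab <- toy_table(list(A = c("p1", "p2"), B = c("p3", "p4")),
                   default_samples("LD", 1, 1:2),
                   function(p, f, e, r) if (p %in% c("p3", "p4") && r == 2) NA else 10)
  g <- build_groups(tab)
  mat <- abundance_matrix(tab, g, "unique_sum")
  expect_true(is.na(mat$abundance[mat$group_id == "B" & mat$replicate == 2]))
  expect_equal(mat$abundance[mat$group_id == "B" & mat$replicate == 1], 20)

  tab_sub <- toy_table(list(A = c("p1", "p2", "p5"), "A;B" = "p9"),
                       one_sample, function(...) 3)
  g_sub <- build_groups(tab_sub)
  expect_warning(abundance_matrix(tab_sub, g_sub, "unique_sum"),
                 "non-quantifiable")
})

test_that("relative abundance matches a brute-force recomputation and is scale invariant", {
  set.seed(11)
  n_prot <- 10
  peps <- lapply(seq_len(n_prot), function(i) sprintf("pr%02d_p%d", i, 1:sample(2:5, 1)))
  names(peps) <- sprintf("PR%02d", seq_len(n_prot))
  vals <- stats::setNames(stats::runif(sum(lengths(peps)), 1, 1000),
                          unlist(peps))
  vals[sample(length(vals), 4)] <- NA  # some nd
  tab <- toy_table(peps, one_sample, abund_from(vals))
  g <- build_groups(tab)
  rel <- relative_abundance(tab, g, "unique_sum")

  denom <- sum(vals, na.rm = TRUE)
  for (acc in names(peps)) {
    expected <- if (all(is.na(vals[peps[[acc]]]))) NA_real_ else
      sum(vals[peps[[acc]]], na.rm = TRUE) / denom
    expect_equal(rel$rel_abundance[rel$group_id == acc], expected)
  }
  expect_lte(sum(rel$rel_abundance, na.rm = TRUE), 1 + 1e-12)

  tab_scaled <- tab
  tab_scaled$abundance <- tab$abundance * 37.5
  rel2 <- relative_abundance(tab_scaled, g, "unique_sum")
  expect_equal(rel2$rel_abundance, rel$rel_abundance)
})

test_that("a single protein owning every peptide of a sample has relative abundance 1", {
  tab <- toy_table(list(A = c("p1", "p2")), one_sample, function(...) 5)
  g <- build_groups(tab)
  expect_equal(relative_abundance(tab, g)$rel_abundance, 1)
})

test_that("an all-nd sample is an error naming the sample", {
  tab <- toy_table(list(A = c("p1", "p2")), default_samples("LD", 1, 1:2),
                   function(p, f, e, r) if (r == 2) NA else 5)
  g <- build_groups(tab)
  expect_error(relative_abundance(tab, g), "LD_1_2",
               class = "coreome_input_error")
})

test_that("replicate and experiment means exclude nd rather than zero-imputing", {
  expect_equal(average_over_replicates(c(2, 4, 6)), 4)
  expect_equal(average_over_replicates(c(2, NA, 6)), 4)
  expect_true(is.na(average_over_replicates(c(NA, NA, NA))))
})

test_that("experiment averages reproduce the published nd-aware values", {
  expect_equal(signif(average_over_experiments(c(5.50e5, 2.30e5, 4.47e4)), 3), 2.75e5)
  expect_equal(signif(average_over_experiments(c(4.57e5, 2.06e6, NA)), 3), 1.26e6)
  expect_equal(signif(average_over_experiments(c(7.79e7, 7.87e6, 7.20e6)), 3), 3.10e7)
})

test_that("mass contributions renormalize to exactly 100 and propagate nd", {
  expect_equal(mass_contribution(75), 100)
  expect_equal(mass_contribution(c(75, 25)), c(75, 25))
  x <- c(5, 3, 2) * 13.7
  expect_equal(sum(mass_contribution(x)), 100, tolerance = 1e-9)
  got <- mass_contribution(c(10, NA, 30))
  expect_true(is.na(got[2]))
  expect_equal(sum(got, na.rm = TRUE), 100)
  expect_error(mass_contribution(c(NA_real_, NA_real_)),
               class = "coreome_input_error")
})

test_that("top3_summary averages replicates then experiments and supports both percentage conventions", {
  samples <- default_samples("LD", 1:2, 1:2)
  vals <- function(p, f, e, r) {
    base <- c(a1 = 100, a2 = 80, b1 = 20, b2 = 10)
    if (p == "b1" && e == 2) NA else base[p] * e
  }
  tab <- toy_table(list(A = c("a1", "a2"), B = c("b1", "b2")), samples, vals)
  g <- build_groups(tab)
  s <- top3_summary(tab, g, target_fraction = "LD")
  a <- s[s$group_id == "A", ]
  expect_equal(a$top3_exp1, 180)
  expect_equal(a$top3_exp2, 360)
  expect_equal(a$average, 270)
  b <- s[s$group_id == "B", ]
  expect_equal(b$top3_exp2, 20)  # b1 nd in experiment 2
  expect_equal(sum(s$mass_contribution), 100, tolerance = 1e-9)

  s2 <- top3_summary(tab, g, convention = "average_of_percents")
  expect_equal(sum(is.na(s2$mass_contribution)), 0)
  expect_false(isTRUE(all.equal(s2$mass_contribution, s$mass_contribution)))
})
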