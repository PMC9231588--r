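# shared fixtures (no cross-group ties, so rank tests stay exact)
fix_g1 <- c(2.1, 3.4, 1.9, 4.2, 3.3, 2.8, 3.9, 2.5, 3.1, 2.7)
fix_g2 <- c(4.8, 5.1, 3.95, 5.6, 4.4, 5.0, 4.35, 5.9, 4.1, 4.6)
fix_g3 <- c(3.0, 3.8, 2.6, 4.5, 3.2, 4.0, 3.5, 2.9, 4.3, 3.6)

test_that("normality gate routes clean and skewed data correctly", {
  para <- vapply(1:100, function(s) {
    set.seed(s)
    g <- list(a = rnorm(30), b = rnorm(30))
    normality_gate(g)$family == "parametric"
  }, TRUE)
  expect_gte(mean(para), 0.90)
  nonp <- vapply(1:100, function(s) {
    set.seed(s)
    g <- list(a = exp(rnorm(30, sd = 1.5)), b = exp(rnorm(30, sd = 1.5)))
    normality_gate(g)$family == "nonparametric"
  }, TRUE)
  expect_gte(mean(nonp), 0.90)
  gate <- normality_gate(list(a = rep(1, 5), b = rnorm(5)))
  expect_equal(gate$family, "nonparametric")
  expect_true(gate$degenerate[["a"]])
  expect_error(normality_gate(list(a = 1:2, b = 1:5)), "n >= 3")
})

test_that("two-group and paired p-values match an independent reference implementation", {
  # reference values computed once with an independent statistics library
  d2 <- tibble::tibble(group = rep(c("WT", "HOM"), each = 10),
                       value = c(fix_g1, fix_g2))
  gate_p <- structure(list(family = "parametric"), class = "normality_gate")
  cmp <- compare_groups(d2, "two_group", metric = "fixture", gate = gate_p)
  expect_equal(cmp$test_used, "student_t")
  expect_equal(cmp$p_overall, 1.617349431663e-05, tolerance = 1e-6)

  gate_n <- structure(list(family = "nonparametric"), class = "normality_gate")
  cmpn <- compare_groups(d2, "two_group", metric = "fixture", gate = gate_n)
  expect_equal(cmpn$test_used, "mann_whitney")
  expect_equal(cmpn$p_overall, 4.330035289788e-05, tolerance = 1e-6)

  dp <- tibble::tibble(id = rep(1:10, 2),
                       condition = rep(c("before", "after"), each = 10),
                       value = c(fix_g1, fix_g3))
  cp <- compare_groups(dp, "paired", metric = "fixture")
  expect_equal(cp$test_used, "paired_t")
  expect_equal(cp$p_overall, 9.671971427442e-03, tolerance = 1e-6)

  same <- tibble::tibble(group = rep(c("a", "b"), each = 3),
                         value = c(1, 2, 3, 1, 2, 3))
  cs <- compare_groups(same, "two_group", gate = gate_p)
  expect_equal(cs$p_overall, 1)
  expect_equal(unname(cs$statistic), 0)
})

test_that("multi-group dispatch matches Kruskal-Wallis/Dunn and Dunnett references", {
  d3 <- tibble::tibble(group = rep(c("WT", "HOM", "HET"), each = 10),
                       value = c(fix_g1, fix_g2, fix_g3))
  gate_n <- structure(list(family = "nonparametric"), class = "normality_gate")
  kw <- compare_groups(d3, "multi_group", reference = "WT", gate = gate_n)
  expect_equal(kw$test_used, "kruskal_dunn")
  expect_equal(kw$p_overall, 1.524937270633e-04, tolerance = 1e-6)
  expect_equal(kw$comparisons$statistic[kw$comparisons$group == "HOM"],
               4.089404089406, tolerance = 1e-6)
  expect_equal(kw$comparisons$p_unadjusted[kw$comparisons$group == "HOM"],
               4.324828484634e-05, tolerance = 1e-6)
  expect_equal(kw$comparisons$p_unadjusted[kw$comparisons$group == "HET"],
               2.132783626614e-01, tolerance = 1e-6)
  expect_true(all(kw$comparisons$p_adjusted >= kw$comparisons$p_unadjusted))

  # tie-corrected Dunn z on a fixture with heavy ties
  h <- list(WT = c(1, 2, 2, 3, 4, 5), HET = c(2, 3, 3, 5, 6, 7),
            HOM = c(4, 5, 6, 6, 7, 8))
  dz <- zebratrax:::dunn_vs_reference(h, "WT")
  expect_equal(dz$statistic[dz$group == "HET"], 1.309995545059,
               tolerance = 1e-6)
  expect_equal(dz$statistic[dz$group == "HOM"], 2.701865811685,
               tolerance = 1e-6)
  expect_equal(dz$p_unadjusted[dz$group == "HOM"], 6.895158410755e-03,
               tolerance = 1e-6)

  gate_p <- structure(list(family = "parametric"), class = "normality_gate")
  dn <- compare_groups(d3, "multi_group", reference = "WT", gate = gate_p)
  expect_equal(dn$test_used, "anova_dunnett")
  # multivariate-t quadrature precision bounds the Dunnett cross-check
  expect_equal(dn$comparisons$p_adjusted[dn$comparisons$group == "HOM"],
               2.83302558e-06, tolerance = 1e-3)
  expect_equal(dn$comparisons$p_adjusted[dn$comparisons$group == "HET"],
               1.33856380e-01, tolerance = 1e-3)
  expect_true(all(dn$comparisons$p_adjusted >=
                    dn$comparisons$p_unadjusted - 1e-12))

  # a 10-pooled-SD shift is unmissable after Dunnett adjustment
  set.seed(99)
  base <- rnorm(20); b2 <- rnorm(20)
  shifted <- rnorm(20) + 10 * sd(c(base, b2))
  dd <- tibble::tibble(group = rep(c("WT", "HET", "HOM"), each = 20),
                       value = c(base, b2, shifted))
  cs <- compare_groups(dd, "multi_group", reference = "WT", gate = gate_p)
  expect_lt(cs$comparisons$p_adjusted[cs$comparisons$group == "HOM"], 1e-4)

  expect_error(compare_groups(d2 <- tibble::tibble(group = "a", value = 1),
                              "multi_group"), "requires")
})

test_that("summaries produce mean/SEM and reproducible bootstrap CIs", {
  s <- summarize_values(c(1, 2, 3), "parametric")
  expect_equal(s$mean, 2)
  expect_equal(s$sem, 1 / sqrt(3), tolerance = 1e-12)
  sc <- summarize_values(rep(4, 10), "parametric")
  expect_equal(sc$sem, 0)

  x <- fix_g1
  got <- summarize_values(x, "nonparametric", n_boot = 2000, seed = 7)
  # brute-force resampling loop under the same seed
  set.seed(7)
  meds <- numeric(2000)
  for (i in 1:2000) meds[i] <- median(x[sample.int(10, 10, replace = TRUE)])
  expect_equal(got$ci_lo, unname(quantile(meds, 0.025)))
  expect_equal(got$ci_hi, unname(quantile(meds, 0.975)))
  expect_error(summarize_values(1), "n >= 2")
})

test_that("count summaries format n/N (p%) with half-up one-decimal rounding", {
  counts <- tibble::tibble(
    label = c(rep("mortality_24hpf", 3), rep("abnormal_48hpf", 3),
              rep("abnormal_72hpf", 3)),
    group = rep(c("WT", "HET", "HOM"), 3),
    numerator = c(2, 8, 54, 0, 5, 6, 2, 10, 2),
    denominator = c(92, 59, 82, 30, 27, 23, 40, 47, 22))
  cs <- count_summary(counts)
  expect_equal(cs$formatted[cs$group == "HOM" & cs$label == "mortality_24hpf"],
               "54/82 (65.9%)")
  expect_equal(cs$formatted[cs$group == "WT" & cs$label == "abnormal_48hpf"],
               "0/30 (0%)")
  expect_equal(cs$formatted[cs$group == "WT" & cs$label == "abnormal_72hpf"],
               "2/40 (5%)")
  expect_equal(count_summary(tibble::tibble(label = "x", group = "g",
                                            numerator = 1,
                                            denominator = 3))$percent, 33.3)
  expect_error(count_summary(tibble::tibble(label = "x", group = "g",
                                            numerator = 5, denominator = 3)),
               "exceeds")
  expect_error(count_summary(tibble::tibble(label = "x", group = "g",
                                            numerator = 1, denominator = 0)),
               "> 0")
})

test_that("significance stars and p formatting follow the reporting thresholds", {
  expect_equal(significance_stars(c(0.3, 0.04, 0.009, 0.0009, 0.00009)),
               c("ns", "*", "**", "***", "****"))
  expect_equal(format_p(0.00004), "<0.0001")
  expect_equal(format_p(0.012345), "0.01234")
})
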