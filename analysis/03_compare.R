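#!/usr/bin/env Rscript

# Step 3 — genotype comparisons for every metric with the standard dispatch
# (Shapiro-Wilk gate; Student's t or Mann-Whitney for two groups), plus the
# early-development count table.
#
# Output: results/comparisons.json, results/report.md,
#         results/early_development.csv

suppressMessages({ library(zebratrax); library(dplyr); library(purrr) })

mdir <- "results/metrics"
stopifnot(dir.exists(mdir))

specs <- list(
  light_dark = c("mean_activity", "ratio_light_to_dark",
                 "ratio_dark_to_light"),
  open_field = c("mean_activity", "thigmo_time", "thigmo_distance"),
  social_juvenile = c("spi_test", "delta_spi"),
  social_adult = c("spi_time", "spi_distance"),
  shoal = "mean_iid"
)

comparisons <- list()
for (paradigm in names(specs)) {
  tab <- readr::read_csv(file.path(mdir, paste0(paradigm, ".csv")),
                         show_col_types = FALSE)
  for (m in specs[[paradigm]]) {
    dat <- tibble(group = tab$genotype, value = tab[[m]])
    cmp <- compare_groups(dat[!is.na(dat$value), ], "two_group",
                          metric = paste(paradigm, m, sep = "."))
    comparisons[[cmp$metric]] <- cmp
    stars <- significance_stars(cmp$p_overall)
    message(sprintf("%-38s %-12s p = %-10s %s", cmp$metric, cmp$test_used,
                    format_p(cmp$p_overall), stars))
  }
}

to_list <- function(cmp) list(
  metric = cmp$metric, test_used = cmp$test_used, family = cmp$family,
  p_overall = cmp$p_overall, summaries = as.data.frame(cmp$summaries),
  alpha = cmp$alpha, two_tailed = cmp$two_tailed)
jsonlite::write_json(map(comparisons, to_list), "results/comparisons.json",
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)

# early-development counts (study inputs) formatted as n/N (p%)
counts <- tibble(
  label = c(rep("mortality_24hpf", 3), rep("abnormal_48hpf", 3),
            rep("abnormal_72hpf", 3)),
  group = rep(c("WT", "HET", "HOM"), 3),
  numerator = c(2, 8, 54, 0, 5, 6, 2, 10, 2),
  denominator = c(92, 59, 82, 30, 27, 23, 40, 47, 22))
readr::write_csv(count_summary(counts), "results/early_development.csv")

# human-readable report
lines <- c("# Genotype comparison report", "",
           "Two-group comparisons (mutant vs wild-type), two-tailed, alpha = 0.05.",
           "")
for (cmp in comparisons) {
  s <- cmp$summaries
  desc <- if (cmp$family == "parametric") {
    paste(sprintf("%s %.3g +/- %.2g (n=%d)", s$group, s$mean, s$sem, s$n),
          collapse = "; ")
  } else {
    paste(sprintf("%s median %.3g [%.3g, %.3g] (n=%d)", s$group, s$median,
                  s$ci_lo, s$ci_hi, s$n), collapse = "; ")
  }
  lines <- c(lines, sprintf("- **%s** (%s): %s — p = %s %s", cmp$metric,
                            cmp$test_used, desc, format_p(cmp$p_overall),
                            significance_stars(cmp$p_overall)))
}
writeLines(lines, "results/report.md")
message("Done: results/comparisons.json, results/report.md, results/early_development.csv")
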