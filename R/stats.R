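#' Normality gate for test dispatch
#'
#' Shapiro-Wilk per group at `alpha`; any rejection (or a degenerate
#' zero-variance group, for which the test is undefined) routes the metric to
#' the nonparametric family.
#'
#' @param groups Named list of numeric vectors, one per group (each n >= 3).
#' @param alpha Per-group significance level of the Shapiro-Wilk test.
#' @return A `normality_gate` list: `family` (`"parametric"` /
#'   `"nonparametric"`), per-group `p_values`, `degenerate` flags.
#' @export
normality_gate <- function(groups, alpha = 0.05) {
  stopifnot(is.list(groups), length(groups) >= 1)
  if (any(vapply(groups, length, 0L) < 3))
    zt_abort("normality gate needs n >= 3 in every group")
  degenerate <- vapply(groups, function(g) sd(g) == 0, TRUE)
  p <- vapply(seq_along(groups), function(i) {
    if (degenerate[i]) return(NA_real_)
    shapiro.test(groups[[i]])$p.value
  }, 0)
  names(p) <- names(groups)
  family <- if (any(degenerate) || any(p < alpha, na.rm = TRUE))
    "nonparametric" else "parametric"
  structure(list(family = family, p_values = p, degenerate = degenerate,
                 alpha = alpha),
            class = "normality_gate")
}

# Dunn's rank-based post-hoc comparisons against a reference group after a
# Kruskal-Wallis test, with tie-corrected pooled variance; adjusted p-values
# are Bonferroni over the (k - 1) reference comparisons
dunn_vs_reference <- function(groups, reference) {
  x <- unlist(groups, use.names = FALSE)
  g <- rep(names(groups), lengths(groups))
  r <- rank(x)
  N <- length(x)
  cnt <- table(x)
  tie_term <- sum(cnt^3 - cnt) / (12 * (N - 1))
  var_term <- N * (N + 1) / 12 - tie_term
  rbar <- tapply(r, g, mean)
  nn <- tapply(r, g, length)
  others <- setdiff(names(groups), reference)
  z <- vapply(others, function(k) {
    (rbar[[k]] - rbar[[reference]]) /
      sqrt(var_term * (1 / nn[[k]] + 1 / nn[[reference]]))
  }, 0)
  p <- 2 * pnorm(-abs(z))
  tibble::tibble(group = others, statistic = unname(z),
                 p_unadjusted = unname(p),
                 p_adjusted = pmin(1, unname(p) * length(others)))
}

# Dunnett's test vs the reference level via multcomp; the quasi-Monte-Carlo
# multivariate-t quadrature is run under a local fixed RNG state so repeated
# calls are reproducible
dunnett_vs_reference <- function(values, groups, reference) {
  f <- stats::relevel(factor(groups), ref = reference)
  dat <- data.frame(value = values, group = f)
  fit <- aov(value ~ group, data = dat)
  gl <- multcomp::glht(fit, linfct = multcomp::mcp(group = "Dunnett"))
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)
  set.seed(20240101)
  sm <- summary(gl)
  un <- summary(gl, test = multcomp::univariate())
  tibble::tibble(
    group = sub("^(.*) - .*$", "\\1", names(sm$test$coefficients)),
    estimate = unname(sm$test$coefficients),
    statistic = unname(sm$test$tstat),
    p_unadjusted = unname(un$test$pvalues),
    p_adjusted = unname(sm$test$pvalues)
  )
}

#' Group comparison with the standard behavioral-phenotyping dispatch
#'
#' Implements the comparison scheme used throughout zebrafish phenotyping
#' reports: normally distributed data (per [normality_gate()]) are compared
#' with Student's t-test (two groups) or one-way ANOVA with Dunnett's
#' multiple-comparisons test against the wild-type reference (three or more
#' groups); non-normal data with Mann-Whitney U (a documented extension of
#' the scheme) or Kruskal-Wallis ANOVA with Dunn's multiple-comparisons
#' test. Paired designs use the paired t-test. All tests are two-tailed.
#' Parametric summaries are mean +/- SEM; nonparametric summaries are median
#' with a seeded percentile-bootstrap 95% CI.
#'
#' @param data A data frame with columns `group` and `value` (for
#'   `design = "paired"`: columns `id`, `condition`, `value` with exactly two
#'   conditions).
#' @param design `"two_group"`, `"multi_group"` (vs reference) or `"paired"`.
#' @param reference Reference group for multi-group comparisons (`"WT"`).
#' @param metric Metric name carried into the report.
#' @param gate Optional precomputed [normality_gate()]; otherwise computed.
#' @param include_summaries Compute per-group summaries (disable in tight
#'   simulation loops where only the dispatch and p-values matter).
#' @return A `group_comparison` object: test used, per-group summaries,
#'   overall and per-comparison p-values.
#' @export
compare_groups <- function(data, design = c("two_group", "multi_group",
                                            "paired"),
                           reference = "WT", metric = "metric", gate = NULL,
                           include_summaries = TRUE) {
  design <- match.arg(design)
  data <- tibble::as_tibble(data)
  if (design == "paired") {
    if (!all(c("id", "condition", "value") %in% names(data)))
      zt_abort("paired design needs columns id, condition, value")
    conds <- unique(data$condition)
    if (length(conds) != 2) zt_abort("paired design needs exactly 2 conditions")
    wide <- tidyr::pivot_wider(data, id_cols = "id",
                               names_from = "condition",
                               values_from = "value")
    x <- wide[[conds[1]]]; y <- wide[[conds[2]]]
    if (anyNA(x) || anyNA(y)) zt_abort("unpaired observations in paired design")
    ht <- t.test(x, y, paired = TRUE)
    summaries <- dplyr::bind_rows(
      cbind(group = conds[1], summarize_values(x, "parametric")),
      cbind(group = conds[2], summarize_values(y, "parametric"))
    )
    return(structure(list(
      metric = metric, design = design, test_used = "paired_t",
      family = "parametric", summaries = tibble::as_tibble(summaries),
      p_overall = ht$p.value, statistic = unname(ht$statistic),
      comparisons = tibble::tibble(group = conds[2],
                                   p_unadjusted = ht$p.value,
                                   p_adjusted = ht$p.value),
      alpha = 0.05, two_tailed = TRUE
    ), class = "group_comparison"))
  }
  if (!all(c("group", "value") %in% names(data)))
    zt_abort("data needs columns group, value")
  groups <- split(data$value, data$group)
  k <- length(groups)
  if (design == "two_group" && k != 2)
    zt_abort("two_group design requires exactly 2 groups")
  if (design == "multi_group") {
    if (k < 3) zt_abort("multi_group design requires >= 3 groups")
    if (!reference %in% names(groups))
      zt_abort(paste0("reference group ", reference, " not present"))
  }
  if (is.null(gate)) gate <- normality_gate(groups)
  fam <- gate$family
  style <- if (fam == "parametric") "parametric" else "nonparametric"
  summaries <- NULL
  if (include_summaries) {
    summaries <- purrr::map_dfr(names(groups), function(g) {
      cbind(group = g, summarize_values(groups[[g]], style, seed = 1L))
    })
    summaries <- tibble::as_tibble(summaries)
  }

  if (design == "two_group") {
    other <- setdiff(names(groups), reference)
    if (length(other) != 1) { reference <- names(groups)[1]; other <- names(groups)[2] }
    if (fam == "parametric") {
      ht <- t.test(groups[[other]], groups[[reference]], var.equal = TRUE)
      test_used <- "student_t"
    } else {
      ht <- suppressWarnings(wilcox.test(groups[[other]], groups[[reference]]))
      test_used <- "mann_whitney"
    }
    comparisons <- tibble::tibble(group = other, p_unadjusted = ht$p.value,
                                  p_adjusted = ht$p.value)
    p_overall <- ht$p.value
    statistic <- unname(ht$statistic)
  } else {
    if (fam == "parametric") {
      fit <- aov(value ~ group,
                 data = data.frame(value = data$value,
                                   group = stats::relevel(factor(data$group),
                                                          ref = reference)))
      p_overall <- summary(fit)[[1]][["Pr(>F)"]][1]
      statistic <- summary(fit)[[1]][["F value"]][1]
      comparisons <- dunnett_vs_reference(data$value, data$group, reference)
      test_used <- "anova_dunnett"
    } else {
      kt <- kruskal.test(groups)
      p_overall <- kt$p.value
      statistic <- unname(kt$statistic)
      comparisons <- dunn_vs_reference(groups, reference)
      test_used <- "kruskal_dunn"
    }
  }
  structure(list(metric = metric, design = design, test_used = test_used,
                 family = fam, gate = gate, summaries = summaries,
                 p_overall = p_overall, statistic = statistic,
                 comparisons = comparisons, reference = reference,
                 alpha = 0.05, two_tailed = TRUE),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> %s: %s (%s), overall p %s\n",
              x$metric, x$test_used, x$family, format_p(x$p_overall)))
  if (!is.null(x$summaries)) print(x$summaries, ...)
  print(x$comparisons, ...)
  invisible(x)
}

#' Per-group summary statistics
#'
#' Mean +/- SEM (`SEM = sd/sqrt(n)`) for parametric summaries, or median with
#' a seeded percentile-bootstrap confidence interval for nonparametric ones.
#'
#' @param x Numeric vector (n >= 2).
#' @param style `"parametric"` or `"nonparametric"`.
#' @param conf Confidence level of the bootstrap CI.
#' @param n_boot Bootstrap resamples.
#' @param seed Seed for the bootstrap.
#' @return One-row tibble: `n`, `mean`, `sem`, `median`, `ci_lo`, `ci_hi`,
#'   `style`.
#' @export
summarize_values <- function(x, style = c("parametric", "nonparametric"),
                             conf = 0.95, n_boot = 10000, seed = 1L) {
  style <- match.arg(style)
  n <- length(x)
  if (n < 2) zt_abort("summaries need n >= 2")
  out <- tibble::tibble(n = n, mean = mean(x), sem = sd(x) / sqrt(n),
                        median = median(x), ci_lo = NA_real_,
                        ci_hi = NA_real_, style = style)
  if (style == "nonparametric") {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    set.seed(seed)
    meds <- vapply(seq_len(n_boot),
                   function(i) median(x[sample.int(n, n, replace = TRUE)]), 0)
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    qs <- quantile(meds, c((1 - conf) / 2, 1 - (1 - conf) / 2), names = FALSE,
                   type = 7)
    out$ci_lo <- qs[1]; out$ci_hi <- qs[2]
  }
  out
}

#' Count table with percentage strings
#'
#' Formats per-group count data (e.g. early-development mortality and
#' abnormal-development rates) as `"n/N (p%)"` with one-decimal half-up
#' rounding; integer-valued percentages render without a decimal.
#'
#' @param counts Data frame with columns `label`, `group`, `numerator`,
#'   `denominator`.
#' @return The input with `percent` (numeric) and `formatted` columns added.
#' @export
count_summary <- function(counts) {
  counts <- tibble::as_tibble(counts)
  need <- c("label", "group", "numerator", "denominator")
  if (!all(need %in% names(counts)))
    zt_abort("counts needs columns label, group, numerator, denominator")
  if (any(counts$denominator <= 0)) zt_abort("denominators must be > 0")
  if (any(counts$numerator > counts$denominator))
    zt_abort("numerator exceeds denominator")
  if (any(counts$numerator < 0)) zt_abort("numerators must be >= 0")
  pct <- round_half_up(100 * counts$numerator / counts$denominator, 1)
  counts$percent <- pct
  counts$formatted <- sprintf("%d/%d (%g%%)", counts$numerator,
                              counts$denominator, pct)
  counts
}

#' Significance formatting
#'
#' `significance_stars()` renders the standard thresholds (`*` p < 0.05,
#' `**` p < 0.01, `***` p < 0.001, `****` p < 0.0001); `format_p()` prints
#' four significant digits, with very small values as `"<0.0001"`.
#'
#' @param p P-value(s).
#' @return Character vector.
#' @export
significance_stars <- function(p) {
  dplyr::case_when(
    is.na(p) ~ "",
    p < 0.0001 ~ "****",
    p < 0.001 ~ "***",
    p < 0.01 ~ "**",
    p < 0.05 ~ "*",
    TRUE ~ "ns"
  )
}

#' @rdname significance_stars
#' @export
format_p <- function(p) {
  ifelse(is.na(p), "NA",
         ifelse(p < 0.0001, "<0.0001", as.character(signif(p, 4))))
}
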