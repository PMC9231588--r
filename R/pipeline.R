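#' Paradigm experiment runners
#'
#' Each runner simulates a cohort with the genotype presets and computes the
#' paradigm's per-fish metrics. Per-fish seeds derive from `seed` plus a
#' running fish index, so every experiment is reproducible from its call
#' alone. These runners are the building blocks used by [run_pipeline()],
#' the analysis scripts and the acceptance checks.
#'
#' @param n Named integer vector of fish per genotype,
#'   e.g. `c(WT = 17, HOM = 17)`.
#' @param seed Base integer seed.
#' @param fps Frame rate (frames/s).
#' @name experiments
NULL

expand_cohort <- function(n) {
  if (is.null(names(n)) || !all(names(n) %in% c("WT", "HET", "HOM")))
    zt_abort("n must be a named vector with names among WT, HET, HOM")
  tibble::tibble(genotype = rep(names(n), n),
                 idx = seq_len(sum(n)))
}

#' @rdname experiments
#' @param schedule Larval light/dark schedule.
#' @param arena Arena override.
#' @export
run_light_dark_experiment <- function(n = c(WT = 20, HOM = 20), seed = 1,
                                      schedule = preset_larval_schedule(),
                                      arena = preset_larval_well(),
                                      fps = 25) {
  cohort <- expand_cohort(n)
  dur <- schedule_duration(schedule)
  base_end <- schedule$epochs$end_s[schedule$epochs$label == "L0"]
  if (!length(base_end)) base_end <- schedule$epochs$end_s[1]
  res <- purrr::map_dfr(seq_len(nrow(cohort)), function(i) {
    gt <- cohort$genotype[i]
    tr <- simulate_fish(genotype_preset(gt, "larva"), arena,
                        schedule = schedule, duration_s = dur, fps = fps,
                        seed = seed + cohort$idx[i],
                        fish_id = sprintf("larva%02d", cohort$idx[i]),
                        genotype = gt)
    ap <- activity_profile(tr, window = c(0, base_end))
    ld <- transition_response(tr, schedule, "light_to_dark")
    dl <- transition_response(tr, schedule, "dark_to_light")
    em <- epoch_mean_activity(tr, schedule)
    tibble::tibble(fish_id = tr$fish_id, genotype = gt,
                   mean_activity = ap$mean_activity,
                   ratio_light_to_dark = ld$mean_ratio,
                   ratio_dark_to_light = dl$mean_ratio,
                   epoch_means = list(em))
  })
  res
}

#' @rdname experiments
#' @param duration_s Recording length (s).
#' @export
run_open_field_experiment <- function(n = c(WT = 25, HOM = 33), seed = 1,
                                      duration_s = 1800, fps = 25) {
  cohort <- expand_cohort(n)
  of <- preset_open_field()
  purrr::map_dfr(seq_len(nrow(cohort)), function(i) {
    gt <- cohort$genotype[i]
    tr <- simulate_fish(genotype_preset(gt, "adult"), of$arena,
                        duration_s = duration_s, fps = fps,
                        seed = seed + cohort$idx[i],
                        fish_id = sprintf("adult%02d", cohort$idx[i]),
                        genotype = gt)
    th <- thigmotaxis(tr, partition = of$partition)
    ap <- activity_profile(tr)
    tibble::tibble(fish_id = tr$fish_id, genotype = gt,
                   mean_activity = ap$mean_activity,
                   thigmo_time = th$time_ratio,
                   thigmo_distance = th$distance_ratio)
  })
}

#' @rdname experiments
#' @param paradigm `"juvenile"` (baseline + test periods) or `"adult"`.
#' @param baseline_s,test_s Period lengths (s).
#' @export
run_social_experiment <- function(paradigm = c("juvenile", "adult"),
                                  n = c(WT = 17, HOM = 17), seed = 1,
                                  baseline_s = 600, test_s = 600, fps = 25) {
  paradigm <- match.arg(paradigm)
  cohort <- expand_cohort(n)
  purrr::map_dfr(seq_len(nrow(cohort)), function(i) {
    gt <- cohort$genotype[i]
    trial <- simulate_social_trial(genotype_preset(gt, "adult"),
                                   paradigm = paradigm,
                                   baseline_s = baseline_s, test_s = test_s,
                                   fps = fps, seed = seed + cohort$idx[i],
                                   fish_id = sprintf("%s%02d", paradigm,
                                                     cohort$idx[i]),
                                   genotype = gt)
    tr <- trial$trajectory
    if (paradigm == "juvenile") {
      pb <- trial$periods[trial$periods$period == "baseline", ]
      pt <- trial$periods[trial$periods$period == "test", ]
      sb <- spi(tr, trial$partition, window = c(pb$start_s, pb$end_s),
                period = "baseline")
      st <- spi(tr, trial$partition, window = c(pt$start_s, pt$end_s),
                period = "test")
      tibble::tibble(fish_id = tr$fish_id, genotype = gt,
                     spi_baseline = sb$spi, spi_test = st$spi,
                     delta_spi = delta_spi(sb, st))
    } else {
      st <- spi(tr, trial$partition, mode = "time")
      sd_ <- spi(tr, trial$partition, mode = "distance")
      tibble::tibble(fish_id = tr$fish_id, genotype = gt,
                     spi_time = st$spi, spi_distance = sd_$spi)
    }
  })
}

#' @rdname experiments
#' @param n_groups Named vector of shoal groups per genotype.
#' @param n_fish Fish per shoal (6 in the standard assay).
#' @export
run_shoaling_experiment <- function(n_groups = c(WT = 9, HOM = 10),
                                    n_fish = 6, seed = 1, duration_s = 1800,
                                    fps = 25) {
  cohort <- expand_cohort(n_groups)
  purrr::map_dfr(seq_len(nrow(cohort)), function(i) {
    gt <- cohort$genotype[i]
    grp <- simulate_shoal(n_fish = n_fish,
                          params = genotype_preset(gt, "adult"),
                          duration_s = duration_s, fps = fps,
                          seed = seed + 1000 * cohort$idx[i], genotype = gt)
    sr <- shoaling_iid(grp)
    tibble::tibble(group_id = sprintf("shoal%02d", cohort$idx[i]),
                   genotype = gt, mean_iid = sr$mean_iid)
  })
}

## ---- pipeline --------------------------------------------------------------

#' Pipeline configuration
#'
#' A run configuration names the paradigms to simulate, the per-genotype
#' group sizes, the base seed and the output directory. `demo_config()`
#' returns a small all-paradigm configuration that runs in seconds.
#'
#' @param paradigms Subset of `"light_dark"`, `"open_field"`,
#'   `"social_juvenile"`, `"social_adult"`, `"shoal"`.
#' @param n Named vector of fish (or shoal groups) per genotype.
#' @param seed Base seed; required whenever simulation is requested.
#' @param out_dir Output directory.
#' @param durations Optional named list of per-paradigm durations (s).
#' @return A `run_config` list.
#' @export
run_config <- function(paradigms, n, seed, out_dir, durations = list()) {
  known <- c("light_dark", "open_field", "social_juvenile", "social_adult",
             "shoal")
  bad <- setdiff(paradigms, known)
  if (length(bad))
    zt_abort(paste0("unknown paradigm(s): ", paste(bad, collapse = ", ")))
  if (is.null(seed)) zt_abort("explicit seed required for simulation")
  structure(list(paradigms = paradigms, n = n, seed = as.integer(seed),
                 out_dir = out_dir, durations = durations),
            class = "run_config")
}

#' @rdname run_config
#' @export
demo_config <- function(out_dir = tempfile("zebratrax_demo"), seed = 42) {
  run_config(
    paradigms = c("light_dark", "open_field", "social_juvenile",
                  "social_adult", "shoal"),
    n = c(WT = 3, HOM = 3), seed = seed, out_dir = out_dir,
    durations = list(light_dark = 2700, open_field = 300,
                     social_juvenile = 120, social_adult = 300, shoal = 120)
  )
}

#' @rdname run_config
#' @param path YAML file with fields `paradigms`, `n`, `seed`, `out_dir`,
#'   optional `durations`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  run_config(paradigms = y$paradigms, n = unlist(y$n), seed = y$seed,
             out_dir = y$out_dir,
             durations = if (is.null(y$durations)) list() else y$durations)
}

pipeline_metric_set <- function(config) {
  d <- function(p, default) {
    v <- config$durations[[p]]
    if (is.null(v)) default else v
  }
  seed <- config$seed
  out <- list()
  if ("light_dark" %in% config$paradigms) {
    sched <- if (d("light_dark", 2700) == 2700) preset_larval_schedule()
             else preset_larval_schedule(cycle_s = d("light_dark", 2700) / 9)
    ld <- run_light_dark_experiment(config$n, seed = seed, schedule = sched)
    out$light_dark <- dplyr::select(ld, -"epoch_means")
  }
  if ("open_field" %in% config$paradigms)
    out$open_field <- run_open_field_experiment(config$n, seed = seed + 10000,
                                                duration_s = d("open_field", 1800))
  if ("social_juvenile" %in% config$paradigms)
    out$social_juvenile <- run_social_experiment(
      "juvenile", config$n, seed = seed + 20000,
      baseline_s = d("social_juvenile", 600) / 2,
      test_s = d("social_juvenile", 600) / 2)
  if ("social_adult" %in% config$paradigms)
    out$social_adult <- run_social_experiment(
      "adult", config$n, seed = seed + 30000,
      test_s = d("social_adult", 1800))
  if ("shoal" %in% config$paradigms)
    out$shoal <- run_shoaling_experiment(config$n, seed = seed + 40000,
                                         duration_s = d("shoal", 1800))
  out
}

pipeline_comparisons <- function(metric_tables) {
  specs <- list(
    light_dark = c("mean_activity", "ratio_light_to_dark",
                   "ratio_dark_to_light"),
    open_field = c("mean_activity", "thigmo_time", "thigmo_distance"),
    social_juvenile = c("spi_test", "delta_spi"),
    social_adult = c("spi_time", "spi_distance"),
    shoal = "mean_iid"
  )
  out <- list()
  for (paradigm in names(metric_tables)) {
    tab <- metric_tables[[paradigm]]
    k <- length(unique(tab$genotype))
    design <- if (k >= 3) "multi_group" else "two_group"
    for (m in specs[[paradigm]]) {
      dat <- tibble::tibble(group = tab$genotype, value = tab[[m]])
      dat <- dat[!is.na(dat$value), ]
      cmp <- compare_groups(dat, design = design,
                            metric = paste(paradigm, m, sep = "."))
      out[[cmp$metric]] <- cmp
    }
  }
  out
}

comparison_to_list <- function(cmp) {
  list(metric = cmp$metric, test_used = cmp$test_used, family = cmp$family,
       p_overall = cmp$p_overall,
       summaries = as.data.frame(cmp$summaries),
       comparisons = as.data.frame(
         cbind(cmp$comparisons,
               stars = significance_stars(cmp$comparisons$p_adjusted))),
       alpha = cmp$alpha, two_tailed = cmp$two_tailed)
}

render_report_md <- function(comparisons) {
  lines <- c("# Behavioral phenotyping report", "")
  for (cmp in comparisons) {
    lines <- c(lines, paste0("## ", cmp$metric), "",
               sprintf("- test: %s (%s family), overall p = %s %s",
                       cmp$test_used, cmp$family, format_p(cmp$p_overall),
                       significance_stars(cmp$p_overall)))
    if (cmp$family == "parametric") {
      for (i in seq_len(nrow(cmp$summaries))) {
        s <- cmp$summaries[i, ]
        lines <- c(lines, sprintf("- %s: mean %.4g +/- SEM %.4g (n = %d)",
                                  s$group, s$mean, s$sem, s$n))
      }
    } else {
      for (i in seq_len(nrow(cmp$summaries))) {
        s <- cmp$summaries[i, ]
        lines <- c(lines,
                   sprintf("- %s: median %.4g (95%% CI %.4g-%.4g, n = %d)",
                           s$group, s$median, s$ci_lo, s$ci_hi, s$n))
      }
    }
    if (!is.null(cmp$comparisons) && nrow(cmp$comparisons)) {
      for (i in seq_len(nrow(cmp$comparisons))) {
        cc <- cmp$comparisons[i, ]
        lines <- c(lines, sprintf("- %s vs reference: adjusted p = %s %s",
                                  cc$group, format_p(cc$p_adjusted),
                                  significance_stars(cc$p_adjusted)))
      }
    }
    if (cmp$test_used == "mann_whitney")
      lines <- c(lines,
                 "- note: Mann-Whitney U is the documented two-group nonparametric fallback")
    lines <- c(lines, "")
  }
  lines
}

#' Run the full pipeline
#'
#' Simulates the configured paradigms, computes every per-fish metric,
#' compares genotypes with the standard dispatch, and writes a metrics CSV,
#' a comparisons JSON, a Markdown report and a run log into
#' `config$out_dir`. Outputs are deterministic given the configuration.
#'
#' @param config A [run_config()] (or path to a YAML config).
#' @return Invisibly, a list with `metrics`, `comparisons` and the output
#'   file paths.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- c(sprintf("zebratrax %s",
                         as.character(utils::packageVersion("zebratrax"))),
                 sprintf("seed: %d", config$seed),
                 sprintf("paradigms: %s",
                         paste(config$paradigms, collapse = ", ")),
                 sprintf("groups: %s",
                         paste(names(config$n), config$n, sep = "=",
                               collapse = ", ")),
                 "settings: 30-s bins; equal-area open-field split; quarter-band juvenile sectors; boundary tie-break = first zone; dropout bridging <= 1 s")
  metrics <- pipeline_metric_set(config)
  log_lines <- c(log_lines,
                 vapply(names(metrics), function(p)
                   sprintf("stage %s: %d rows", p, nrow(metrics[[p]])), ""))
  comparisons <- pipeline_comparisons(metrics)
  metrics_long <- purrr::map_dfr(names(metrics), function(p) {
    tab <- metrics[[p]]
    idcol <- if ("fish_id" %in% names(tab)) "fish_id" else "group_id"
    tidyr::pivot_longer(tab,
                        cols = -dplyr::all_of(c(idcol, "genotype")),
                        names_to = "metric", values_to = "value") |>
      dplyr::mutate(paradigm = p, id = .data[[idcol]], .keep = "unused") |>
      dplyr::select("paradigm", "id", "genotype", "metric", "value")
  })
  paths <- list(
    metrics = file.path(config$out_dir, "metrics.csv"),
    comparisons = file.path(config$out_dir, "comparisons.json"),
    report = file.path(config$out_dir, "report.md"),
    log = file.path(config$out_dir, "run_log.txt")
  )
  readr::write_csv(metrics_long, paths$metrics, progress = FALSE)
  jsonlite::write_json(lapply(comparisons, comparison_to_list),
                       paths$comparisons, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  writeLines(render_report_md(comparisons), paths$report)
  writeLines(log_lines, paths$log)
  invisible(list(metrics = metrics, comparisons = comparisons,
                 paths = paths))
}
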