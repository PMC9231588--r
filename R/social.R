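#' Social preference index (SPI)
#'
#' Normalized dwell asymmetry between the sector adjacent to conspecifics
#' and the opposite empty sector:
#' `SPI = (conspecific - empty) / (conspecific + empty)`, computed on dwell
#' time or in-sector path length. Time spent outside both sectors does not
#' enter the denominator. SPI ranges from -1 (all dwell on the empty side)
#' to +1 (all dwell on the conspecific side); 0 is indifference.
#'
#' @param traj A [trajectory()].
#' @param partition Partition naming zones `conspecific` and `empty`.
#' @param window Optional `c(start_s, end_s)` period restriction.
#' @param mode `"time"` or `"distance"`.
#' @param period Label stored with the result (`"baseline"`, `"test"`, ...).
#' @return A tibble row: `fish_id`, `genotype`, `period`, `mode`, `spi`,
#'   `dwell_conspecific`, `dwell_empty`, `flagged` (zero combined dwell).
#' @export
spi <- function(traj, partition, window = NULL, mode = c("time", "distance"),
                period = "test") {
  mode <- match.arg(mode)
  if (!inherits(traj, "trajectory"))
    zt_abort("SPI needs per-frame trajectory input (binned-only records are unsupported)",
             "zebratrax_unsupported_input")
  if (!all(c("conspecific", "empty") %in% names(partition$zones)))
    zt_abort("partition must define zones 'conspecific' and 'empty'")
  occ <- zone_occupancy(traj, partition, window = window)
  col <- if (mode == "time") "time_s" else "distance_mm"
  dc <- occ[[col]][occ$zone == "conspecific"]
  de <- occ[[col]][occ$zone == "empty"]
  denom <- dc + de
  tibble::tibble(
    fish_id = traj$fish_id, genotype = traj$genotype, period = period,
    mode = mode,
    spi = if (denom > 0) (dc - de) / denom else NA_real_,
    dwell_conspecific = dc, dwell_empty = de,
    flagged = denom <= 0
  )
}

#' Change in social preference between baseline and test periods
#'
#' @param baseline,test SPI rows (as returned by [spi()]) for the same fish
#'   and mode, with periods `baseline` and `test`.
#' @return `spi_test - spi_baseline` (in `[-2, 2]`), or `NA` if either SPI is
#'   undefined.
#' @export
delta_spi <- function(baseline, test) {
  if (!identical(baseline$fish_id, test$fish_id) ||
      !identical(baseline$mode, test$mode))
    zt_abort("baseline and test SPI must be from the same fish and mode")
  if (is.na(baseline$spi) || is.na(test$spi)) return(NA_real_)
  test$spi - baseline$spi
}

#' Shoaling cohesion: mean inter-individual distance
#'
#' For every frame with at least two validly tracked fish, the mean over all
#' `n(n-1)/2` unordered pairwise Euclidean distances; `mean_iid` averages
#' these per-frame means over frames.
#'
#' @param group A [group_recording()] of time-aligned trajectories.
#' @return A `shoal_result`: list with `n_fish`, `per_frame` (tibble `t`,
#'   `iid`, `n_valid`) and `mean_iid` (mm).
#' @export
shoaling_iid <- function(group) {
  stopifnot(inherits(group, "group_recording"))
  trajs <- group$trajectories
  n <- length(trajs)
  nf <- min(vapply(trajs, function(tr) nrow(tr$samples), 0L))
  X <- vapply(trajs, function(tr) tr$samples$x[seq_len(nf)], numeric(nf))
  Y <- vapply(trajs, function(tr) tr$samples$y[seq_len(nf)], numeric(nf))
  V <- vapply(trajs, function(tr) tr$samples$valid[seq_len(nf)], logical(nf))
  sum_d <- numeric(nf)
  n_pair <- numeric(nf)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ok <- V[, i] & V[, j]
      d <- sqrt((X[, i] - X[, j])^2 + (Y[, i] - Y[, j])^2)
      sum_d <- sum_d + ifelse(ok, d, 0)
      n_pair <- n_pair + ok
    }
  }
  usable <- n_pair >= 1
  if (!any(usable)) zt_abort("no frame with at least 2 valid fish")
  per_frame <- tibble::tibble(
    t = trajs[[1]]$samples$t[seq_len(nf)][usable],
    iid = (sum_d / pmax(n_pair, 1))[usable],
    n_valid = rowSums(V)[usable]
  )
  structure(list(n_fish = n, per_frame = per_frame,
                 mean_iid = mean(per_frame$iid)),
            class = "shoal_result")
}

#' @export
print.shoal_result <- function(x, ...) {
  cat(sprintf("<shoal_result> %d fish, %d frames, mean inter-individual distance %.1f mm\n",
              x$n_fish, nrow(x$per_frame), x$mean_iid))
  invisible(x)
}
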