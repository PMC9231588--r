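#' Activity profile (distance per 30-s bin)
#'
#' General locomotor activity is quantified as average distance moved per
#' 30-s bin over a stated window (for the larval assay: the initial 15-min
#' light period before the dark/light cycles).
#'
#' @param traj A [trajectory()].
#' @param window `c(start_s, end_s)`; only bins lying entirely inside the
#'   window contribute.
#' @param bin_s Bin width in seconds.
#' @return An `activity_profile`: list with `fish_id`, `genotype`, `bins`
#'   (tibble of per-bin distances), `window` and `mean_activity`
#'   (mm per `bin_s`).
#' @export
activity_profile <- function(traj, window = c(0, traj_duration(traj)),
                             bin_s = 30) {
  if (diff(window) < bin_s) zt_abort("window shorter than one bin")
  bins <- binned_distance(traj, bin_s = bin_s)
  keep <- bins$bin_start_s >= window[1] - 1e-9 &
    bins$bin_start_s + bin_s <= window[2] + 1e-9
  bins <- bins[keep, , drop = FALSE]
  structure(list(fish_id = traj$fish_id, genotype = traj$genotype,
                 bins = bins, window = window, bin_s = bin_s,
                 mean_activity = mean(bins$distance_mm)),
            class = "activity_profile")
}

#' @export
print.activity_profile <- function(x, ...) {
  cat(sprintf("<activity_profile> fish %s (%s): %.1f mm per %g s over %d bins\n",
              x$fish_id, x$genotype, x$mean_activity, x$bin_s, nrow(x$bins)))
  invisible(x)
}

#' Mean activity per schedule epoch
#'
#' Average distance per 30-s bin within each labelled epoch of the
#' illumination schedule (the standard larval report covers `L0` and the
#' three dark/light cycles `D1, L1, D2, L2, D3, L3`).
#'
#' @param traj A [trajectory()].
#' @param schedule A [light_schedule()].
#' @param labels Epoch labels to report (default: all in the schedule).
#' @param bin_s Bin width (s).
#' @return Tibble with `epoch`, `illumination`, `mean_mm_per_bin`, `n_bins`,
#'   `flagged` (no complete bin in the epoch).
#' @export
epoch_mean_activity <- function(traj, schedule, labels = NULL, bin_s = 30) {
  stopifnot(inherits(schedule, "light_schedule"))
  e <- schedule$epochs
  if (is.null(labels)) labels <- e$label
  if (!all(labels %in% e$label))
    zt_abort(paste0("schedule lacks epoch(s): ",
                    paste(setdiff(labels, e$label), collapse = ", ")))
  bins <- binned_distance(traj, bin_s = bin_s)
  purrr::map_dfr(labels, function(lb) {
    row <- e[e$label == lb, ]
    keep <- bins$bin_start_s >= row$start_s - 1e-9 &
      bins$bin_start_s + bin_s <= row$end_s + 1e-9
    tibble::tibble(
      epoch = lb, illumination = row$illumination,
      mean_mm_per_bin = if (any(keep)) mean(bins$distance_mm[keep]) else NA_real_,
      n_bins = sum(keep), flagged = !any(keep)
    )
  })
}

#' Visual motor response to illumination transitions
#'
#' For every illumination transition of the requested direction, computes
#' mean swimming speed in the 30-s windows before (`[t - w, t)`) and after
#' (`[t, t + w)`) the transition, their after/before ratio, and the mean
#' ratio across the (three) same-direction transitions. A ratio is undefined
#' (flagged, excluded from the mean) when the pre-transition speed is zero.
#'
#' @param traj A [trajectory()].
#' @param schedule A [light_schedule()] with transitions.
#' @param direction `"light_to_dark"` or `"dark_to_light"`.
#' @param window_s Window half-width (s).
#' @return A `transition_response`: list with `fish_id`, `direction`,
#'   `per_transition` (tibble: `time_s`, `v_before`, `v_after`, `ratio`) and
#'   `mean_ratio`.
#' @export
transition_response <- function(traj, schedule,
                                direction = c("light_to_dark", "dark_to_light"),
                                window_s = 30) {
  direction <- match.arg(direction)
  tr <- schedule$transitions
  tr <- tr[tr$direction == direction, , drop = FALSE]
  if (nrow(tr) == 0)
    zt_abort(paste0("no transitions of direction ", direction))
  dur <- traj_duration(traj)
  if (any(tr$time_s - window_s < -1e-9 | tr$time_s + window_s > dur + 1e-9))
    zt_abort("transition windows extend beyond the recording")
  per <- purrr::map_dfr(tr$time_s, function(tt) {
    vb <- mean_speed(traj, c(tt - window_s, tt))
    va <- mean_speed(traj, c(tt, tt + window_s))
    tibble::tibble(time_s = tt, v_before = vb, v_after = va,
                   ratio = ifelse(is.na(vb) | vb <= 0, NA_real_, va / vb))
  })
  structure(list(fish_id = traj$fish_id, genotype = traj$genotype,
                 direction = direction, window_s = window_s,
                 per_transition = per,
                 mean_ratio = if (all(is.na(per$ratio))) NA_real_
                              else mean(per$ratio, na.rm = TRUE)),
            class = "transition_response")
}

#' @export
print.transition_response <- function(x, ...) {
  cat(sprintf("<transition_response> fish %s, %s: mean after/before ratio %.3f over %d transitions\n",
              x$fish_id, x$direction, x$mean_ratio,
              sum(!is.na(x$per_transition$ratio))))
  invisible(x)
}
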