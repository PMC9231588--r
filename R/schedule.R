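#' Illumination schedules
#'
#' A light schedule is an ordered set of labelled, contiguous epochs, each
#' either `light` (100 lx by default) or `dark` (0 lx). Transitions are
#' derived at every epoch boundary where the illumination changes.
#'
#' @param epochs A data frame with columns `label`, `start_s`, `end_s`,
#'   `illumination` (`"light"`/`"dark"`) and optionally `lux`.
#' @return A `light_schedule` object: the epoch table plus a `transitions`
#'   tibble (`time_s`, `direction`).
#' @examples
#' sched <- preset_larval_schedule()
#' sched$transitions
#' @export
light_schedule <- function(epochs) {
  epochs <- tibble::as_tibble(epochs)
  need <- c("label", "start_s", "end_s", "illumination")
  if (!all(need %in% names(epochs))) zt_abort("epochs must have label, start_s, end_s, illumination")
  if (nrow(epochs) == 0) zt_abort("schedule has no epochs")
  if (!all(epochs$illumination %in% c("light", "dark")))
    zt_abort("illumination must be 'light' or 'dark'")
  if (!"lux" %in% names(epochs))
    epochs$lux <- ifelse(epochs$illumination == "light", 100, 0)
  if (any(epochs$end_s <= epochs$start_s)) zt_abort("epochs must have positive duration")
  if (nrow(epochs) > 1 &&
      any(abs(epochs$start_s[-1] - epochs$end_s[-nrow(epochs)]) > 1e-9))
    zt_abort("epochs must be contiguous and non-overlapping")
  n <- nrow(epochs)
  tr <- tibble::tibble(time_s = numeric(), direction = character())
  if (n > 1) {
    chg <- which(epochs$illumination[-n] != epochs$illumination[-1])
    tr <- tibble::tibble(
      time_s = epochs$end_s[chg],
      direction = ifelse(epochs$illumination[chg] == "light",
                         "light_to_dark", "dark_to_light")
    )
  }
  structure(list(epochs = epochs, transitions = tr), class = "light_schedule")
}

#' @export
print.light_schedule <- function(x, ...) {
  cat(sprintf("<light_schedule> %d epochs, %g-%g s, %d transitions\n",
              nrow(x$epochs), min(x$epochs$start_s), max(x$epochs$end_s),
              nrow(x$transitions)))
  print(x$epochs, ...)
  invisible(x)
}

schedule_duration <- function(schedule) {
  max(schedule$epochs$end_s) - min(schedule$epochs$start_s)
}

#' Epoch label at given times
#'
#' @param schedule A [light_schedule()].
#' @param t Times (s); times beyond the schedule map to its last epoch.
#' @return Character vector of epoch labels.
#' @export
schedule_epoch_of <- function(schedule, t) {
  e <- schedule$epochs
  idx <- findInterval(t, e$start_s)
  idx[idx < 1] <- 1
  idx[idx > nrow(e)] <- nrow(e)
  e$label[idx]
}

# illumination at each time point; times past the last epoch keep its state
schedule_illumination_at <- function(schedule, t) {
  e <- schedule$epochs
  idx <- findInterval(t, e$start_s, rightmost.closed = FALSE)
  idx[idx < 1] <- 1
  idx[idx > nrow(e)] <- nrow(e)
  e$illumination[idx]
}

#' Default larval light/dark schedule
#'
#' 45 minutes at the standard larval protocol: a 15-min light period split as
#' `baseline` (first 10 min) and `L0` (last 5 min), followed by three
#' dark/light cycles of 5 min each (`D1, L1, D2, L2, D3, L3`). Lights-off
#' transitions fall at 900, 1500 and 2100 s; lights-on at 1200, 1800 and
#' 2400 s.
#'
#' @param cycle_s Epoch length of each dark/light half-cycle (s).
#' @export
preset_larval_schedule <- function(cycle_s = 300) {
  lab <- c("baseline", "L0", "D1", "L1", "D2", "L2", "D3", "L3")
  dur <- c(2 * cycle_s, cycle_s, rep(cycle_s, 6))
  end <- cumsum(dur)
  light_schedule(tibble::tibble(
    label = lab,
    start_s = c(0, end[-length(end)]),
    end_s = end,
    illumination = c("light", "light", rep(c("dark", "light"), 3))
  ))
}

#' @rdname preset_larval_schedule
#' @param duration_s Total duration of a constant-light schedule (s).
#' @param label Epoch label for the single epoch.
#' @export
constant_light_schedule <- function(duration_s, label = "baseline") {
  light_schedule(tibble::tibble(label = label, start_s = 0, end_s = duration_s,
                                illumination = "light"))
}
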