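#' Fish trajectories
#'
#' A trajectory holds the per-frame positional signal of one fish: strictly
#' increasing sample times, positions in arena-local millimetres, and a
#' per-frame tracking-success flag. Sampling must be near-uniform (mean
#' interval within 10% of `1/fps`) and all valid samples must lie inside the
#' arena.
#'
#' @param fish_id Identifier of the fish.
#' @param samples Data frame with columns `t` (s), `x`, `y` (mm) and
#'   optionally `valid` (logical or 0/1; defaults to all valid).
#' @param fps Nominal frame rate (frames per second; 25 for the standard
#'   video setup).
#' @param arena The [arena_rect()]/[arena_circle()] the fish was tracked in.
#' @param genotype One of `"WT"`, `"HET"`, `"HOM"`.
#' @return An object of class `trajectory`.
#' @export
trajectory <- function(fish_id, samples, fps, arena, genotype = "WT") {
  stopifnot(inherits(arena, "arena"))
  samples <- tibble::as_tibble(samples)
  if (!all(c("t", "x", "y") %in% names(samples)))
    zt_abort("samples must have columns t, x, y")
  if (!"valid" %in% names(samples)) samples$valid <- TRUE
  samples$valid <- as.logical(samples$valid)
  if (nrow(samples) < 2) zt_abort("trajectory needs at least 2 samples")
  if (any(samples$t < 0)) zt_abort("sample times must be >= 0")
  dt <- diff(samples$t)
  if (any(dt <= 0))
    zt_abort(paste0("non-monotone timestamps for fish ", fish_id),
             "zebratrax_nonmonotone_time")
  if (abs(mean(dt) - 1 / fps) > 0.1 / fps)
    zt_abort("mean sampling interval deviates more than 10% from 1/fps")
  v <- samples$valid
  if (any(v & !(is.finite(samples$x) & is.finite(samples$y))))
    zt_abort("valid samples must have finite coordinates")
  if (!all(arena_contains(arena, samples$x[v], samples$y[v], tol = 1e-6)))
    zt_abort("valid samples outside the arena", "zebratrax_out_of_arena")
  if (!genotype %in% c("WT", "HET", "HOM"))
    zt_abort("genotype must be WT, HET or HOM")
  structure(list(fish_id = fish_id, genotype = genotype, fps = fps,
                 arena = arena, samples = samples),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> fish %s (%s), %d frames @ %g fps, %.1f s, %d invalid\n",
              x$fish_id, x$genotype, nrow(x$samples), x$fps,
              traj_duration(x), sum(!x$samples$valid)))
  invisible(x)
}

# nominal duration: one frame interval per sample
traj_duration <- function(traj) nrow(traj$samples) / traj$fps

#' Bridge short tracking dropouts
#'
#' Invalid runs no longer than `max_gap_s` with valid samples on both sides
#' are filled by linear interpolation and marked valid; longer runs are left
#' invalid and stay excluded from time and distance accrual.
#'
#' @param traj A [trajectory()].
#' @param max_gap_s Longest gap (s) to bridge.
#' @return The trajectory with short gaps interpolated.
#' @export
interpolate_dropouts <- function(traj, max_gap_s = 1) {
  s <- traj$samples
  bad <- !s$valid
  if (!any(bad)) return(traj)
  r <- rle(bad)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  for (k in which(r$values)) {
    i0 <- starts[k]; i1 <- ends[k]
    if (i0 == 1 || i1 == nrow(s)) next           # no anchor on one side
    if (s$t[i1 + 1] - s$t[i0 - 1] > max_gap_s + 1 / traj$fps) next
    idx <- i0:i1
    w <- (s$t[idx] - s$t[i0 - 1]) / (s$t[i1 + 1] - s$t[i0 - 1])
    s$x[idx] <- s$x[i0 - 1] + w * (s$x[i1 + 1] - s$x[i0 - 1])
    s$y[idx] <- s$y[i0 - 1] + w * (s$y[i1 + 1] - s$y[i0 - 1])
    s$valid[idx] <- TRUE
  }
  traj$samples <- s
  traj
}

# step table: one row per consecutive-sample step, with the left endpoint's
# time/position; steps touching an invalid endpoint are dropped
traj_steps <- function(traj) {
  s <- traj$samples
  n <- nrow(s)
  ok <- s$valid[-n] & s$valid[-1]
  tibble::tibble(
    t = s$t[-n][ok], x = s$x[-n][ok], y = s$y[-n][ok],
    len = sqrt(diff(s$x)^2 + diff(s$y)^2)[ok],
    dt = diff(s$t)[ok]
  )
}

#' Total path length
#'
#' Sum of Euclidean step lengths between consecutive valid samples, in mm.
#' Steps adjacent to unbridged dropouts are excluded.
#'
#' @param traj A [trajectory()].
#' @return Path length in millimetres.
#' @export
path_length <- function(traj) {
  if (!any(traj$samples$valid)) zt_abort("no valid samples")
  sum(traj_steps(traj)$len)
}

#' Distance moved per time bin
#'
#' Accumulates step lengths into consecutive bins of `bin_s` seconds from the
#' start of the recording (the standard activity readout uses 30-s bins).
#' Only complete bins are returned; a bin with more than 20% of its frames
#' missing is flagged.
#'
#' @param traj A [trajectory()].
#' @param bin_s Bin width in seconds.
#' @return A tibble with `bin_start_s`, `distance_mm`, `n_frames`,
#'   `frac_missing` and `flagged`.
#' @export
binned_distance <- function(traj, bin_s = 30) {
  if (bin_s <= 0) zt_abort("bin_s must be > 0")
  dur <- traj_duration(traj)
  if (dur < bin_s - 1e-9) zt_abort("recording shorter than one bin")
  t0 <- traj$samples$t[1]
  n_bins <- floor(dur / bin_s + 1e-9)
  frames_per_bin <- bin_s * traj$fps
  st <- traj_steps(traj)
  bin <- floor((st$t - t0) / bin_s + 1e-12)
  keep <- bin < n_bins
  d <- vapply(seq_len(n_bins) - 1L,
              function(b) sum(st$len[keep & bin == b]), 0)
  sb <- floor((traj$samples$t - t0) / bin_s + 1e-12)
  miss <- vapply(seq_len(n_bins) - 1L,
                 function(b) sum(!traj$samples$valid[sb == b]), 0L)
  tibble::tibble(
    bin_start_s = t0 + (seq_len(n_bins) - 1L) * bin_s,
    distance_mm = d,
    n_frames = as.integer(round(frames_per_bin)) - miss,
    frac_missing = miss / frames_per_bin,
    flagged = miss / frames_per_bin > 0.2
  )
}

#' Dwell time and path length per zone
#'
#' Classifies every valid frame by partition zone and accrues dwell time
#' (frame count x frame interval) and in-zone path length (each step is
#' attributed to the zone of its starting frame).
#'
#' @param traj A [trajectory()].
#' @param partition An [arena_partition()].
#' @param window Optional `c(start_s, end_s)`; frames with
#'   `start_s <= t < end_s` are included.
#' @return A tibble with one row per zone: `zone`, `time_s`, `distance_mm`.
#' @export
zone_occupancy <- function(traj, partition, window = NULL) {
  stopifnot(inherits(partition, "arena_partition"))
  s <- traj$samples
  dt <- 1 / traj$fps
  if (!is.null(window)) {
    if (window[2] <= window[1]) zt_abort("empty window")
    in_w <- s$t >= window[1] & s$t < window[2]
  } else {
    in_w <- rep(TRUE, nrow(s))
  }
  use <- in_w & s$valid
  zn <- names(partition$zones)
  cl <- rep(NA_character_, nrow(s))
  cl[use] <- classify_points(s$x[use], s$y[use], partition)
  time_s <- vapply(zn, function(z) sum(cl == z, na.rm = TRUE) * dt, 0)
  st <- traj_steps(traj)
  stw <- if (is.null(window)) rep(TRUE, nrow(st)) else
    st$t >= window[1] & st$t < window[2]
  scl <- rep(NA_character_, nrow(st))
  scl[stw] <- classify_points(st$x[stw], st$y[stw], partition)
  dist <- vapply(zn, function(z) sum(st$len[stw][scl[stw] == z], na.rm = TRUE), 0)
  tibble::tibble(zone = zn, time_s = unname(time_s), distance_mm = unname(dist))
}

#' Split a trajectory along an illumination schedule
#'
#' Each sample with `start_s <= t < end_s` of an epoch is assigned to that
#' epoch; the slices are disjoint and cover the scheduled span.
#'
#' @param traj A [trajectory()].
#' @param schedule A [light_schedule()].
#' @return Named list of trajectory slices, one per epoch label.
#' @export
segment_epochs <- function(traj, schedule) {
  stopifnot(inherits(schedule, "light_schedule"))
  if (schedule_duration(schedule) > traj_duration(traj) + 1e-9)
    zt_abort("schedule longer than recording")
  e <- schedule$epochs
  out <- vector("list", nrow(e))
  names(out) <- e$label
  for (i in seq_len(nrow(e))) {
    idx <- traj$samples$t >= e$start_s[i] & traj$samples$t < e$end_s[i]
    sl <- traj
    sl$samples <- traj$samples[idx, , drop = FALSE]
    out[[i]] <- sl
  }
  out
}

# mean swimming speed (mm/s) over a half-open window [start, end):
# summed step lengths divided by the time covered by counted steps
mean_speed <- function(traj, window) {
  st <- traj_steps(traj)
  use <- st$t >= window[1] & st$t < window[2]
  tt <- sum(st$dt[use])
  if (tt <= 0) return(NA_real_)
  sum(st$len[use]) / tt
}
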