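#' Thigmotaxis index
#'
#' Fraction of time (and/or path length) spent in the peripheral zone of an
#' open-field arena divided into two equal-area concentric zones — the
#' standard "wall-hugging" anxiety index. Values near 0.5 indicate no wall
#' preference under the equal-area split; anxious fish score higher.
#'
#' @param traj A [trajectory()] in a rectangular arena.
#' @param partition Optional covering partition with zones `center` and
#'   `periphery`; defaults to the equal-area split of the trajectory's arena.
#' @param mode `"time"`, `"distance"` or `"both"`.
#' @return A tibble row: `fish_id`, `genotype`, `time_ratio`,
#'   `distance_ratio` (NA when not requested), `flagged` (no valid
#'   time/distance to normalize by).
#' @export
thigmotaxis <- function(traj, partition = NULL,
                        mode = c("both", "time", "distance")) {
  mode <- match.arg(mode)
  if (!inherits(traj, "trajectory"))
    zt_abort("thigmotaxis needs per-frame trajectory input (binned-only records are unsupported)",
             "zebratrax_unsupported_input")
  if (is.null(partition)) {
    arena <- traj$arena
    if (arena$shape != "rectangle")
      zt_abort("default thigmotaxis split requires a rectangular arena")
    s <- 1 / sqrt(2)
    cx <- arena$width * (1 - s) / 2
    cy <- arena$height * (1 - s) / 2
    center <- zone_rect("center", cx, arena$width - cx, cy, arena$height - cy)
    partition <- arena_partition(
      arena, list(center, zone_complement("periphery", center)),
      coverage = TRUE)
  }
  if (!all(c("center", "periphery") %in% names(partition$zones)))
    zt_abort("partition must define zones 'center' and 'periphery'")
  occ <- zone_occupancy(traj, partition)
  tot_t <- sum(occ$time_s)
  tot_d <- sum(occ$distance_mm)
  per <- occ[occ$zone == "periphery", ]
  time_ratio <- if (mode %in% c("both", "time") && tot_t > 0)
    per$time_s / tot_t else NA_real_
  distance_ratio <- if (mode %in% c("both", "distance") && tot_d > 0)
    per$distance_mm / tot_d else NA_real_
  flagged <- (mode %in% c("both", "time") && tot_t <= 0) ||
    (mode %in% c("both", "distance") && tot_d <= 0)
  tibble::tibble(fish_id = traj$fish_id, genotype = traj$genotype,
                 time_ratio = time_ratio, distance_ratio = distance_ratio,
                 flagged = flagged)
}
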