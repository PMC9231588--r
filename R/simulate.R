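#' Behavioral parameters of the trajectory simulator
#'
#' Parameters of the discrete-time correlated random walk used to emulate a
#' swimming fish. Speed follows an Euler-discretized mean-reverting process
#' around `mu_speed`, modulated multiplicatively by illumination (`g_dark` in
#' dark epochs) and by a transient startle boost after every illumination
#' transition; heading evolves with wrapped-Gaussian persistence noise plus
#' turn biases toward the nearest wall, toward the conspecific side, and
#' toward the shoal centroid.
#'
#' @param mu_speed Baseline mean speed (mm/s).
#' @param sigma_speed Speed fluctuation scale (mm/s).
#' @param tau_speed Speed relaxation time (s).
#' @param kappa_heading Heading persistence in `[0, 1)`: the mean resultant
#'   length of the per-frame turning-angle distribution (wrapped normal with
#'   `sd = sqrt(-2 log kappa_heading)`).
#' @param kappa_wall Wall-attraction turn-rate gain (rad/s at right angles).
#' @param g_dark Multiplicative speed gain in dark epochs (dimensionless).
#' @param startle_gain Peak relative speed boost at illumination transitions.
#' @param tau_startle Startle decay time constant (s).
#' @param kappa_social Turn-rate gain toward the conspecific-side boundary
#'   (rad/s).
#' @param kappa_cohesion Turn-rate gain toward the shoal centroid (rad/s).
#' @return A `behavior_params` object.
#' @export
behavior_params <- function(mu_speed, sigma_speed = 0, tau_speed = 2,
                            kappa_heading = 0.98, kappa_wall = 0,
                            g_dark = 1, startle_gain = 0, tau_startle = 10,
                            kappa_social = 0, kappa_cohesion = 0) {
  p <- list(mu_speed = mu_speed, sigma_speed = sigma_speed,
            tau_speed = tau_speed, kappa_heading = kappa_heading,
            kappa_wall = kappa_wall, g_dark = g_dark,
            startle_gain = startle_gain, tau_startle = tau_startle,
            kappa_social = kappa_social, kappa_cohesion = kappa_cohesion)
  num <- vapply(p, is.numeric, TRUE)
  if (!all(num) || !all(vapply(p, function(v) all(is.finite(v)), TRUE)))
    zt_abort("all behavior parameters must be finite numbers")
  if (mu_speed < 0 || sigma_speed < 0 || tau_speed <= 0 ||
      kappa_heading < 0 || kappa_heading >= 1 || kappa_wall < 0 ||
      g_dark < 0 || startle_gain < 0 || tau_startle <= 0 ||
      kappa_cohesion < 0)
    zt_abort("behavior parameter out of range")
  structure(p, class = "behavior_params")
}

# documented preset constants; the literature constrains effect DIRECTIONS
# (mutants: slower, more wall-bound, stronger startle, weaker social
# attraction and cohesion), magnitudes are implementation choices anchored to
# the reported group-mean activity (mm per 30 s / 30)
.preset_table <- function() {
  tibble::tribble(
    ~stage, ~genotype, ~mu_speed, ~g_dark, ~startle_gain, ~kappa_wall, ~kappa_social, ~kappa_cohesion,
    "larva", "WT",  2.72, 1.5, 1.0, 0.02, 0.35, 0.60,
    "larva", "HET", 2.13, 1.7, 1.5, 0.03, 0.18, 0.30,
    "larva", "HOM", 1.83, 2.0, 2.5, 0.05, 0.07, 0.05,
    "adult", "WT",  5.17, 1.5, 1.0, 0.18, 0.35, 0.60,
    "adult", "HET", 4.60, 1.7, 1.5, 0.22, 0.18, 0.30,
    "adult", "HOM", 4.11, 2.0, 2.5, 0.28, 0.07, 0.05
  )
}

#' Genotype presets
#'
#' Ready-made [behavior_params()] for wild-type (`WT`), heterozygous (`HET`)
#' and homozygous-mutant (`HOM`) fish at two life stages. The presets encode
#' the reported effect directions — mutants swim slower, hug walls more,
#' startle harder at light transitions, and show weaker social attraction
#' and shoal cohesion — with magnitudes documented in the methods vignette.
#'
#' @param genotype `"WT"`, `"HET"` or `"HOM"`.
#' @param stage `"larva"` (5 dpf assays) or `"adult"`.
#' @return A [behavior_params()] object.
#' @export
genotype_preset <- function(genotype = c("WT", "HET", "HOM"),
                            stage = c("larva", "adult")) {
  genotype <- match.arg(genotype)
  stage <- match.arg(stage)
  row <- dplyr::filter(.preset_table(), .data$stage == !!stage,
                       .data$genotype == !!genotype)
  behavior_params(
    mu_speed = row$mu_speed, sigma_speed = 0.35 * row$mu_speed,
    tau_speed = 2, kappa_heading = 0.98, kappa_wall = row$kappa_wall,
    g_dark = row$g_dark, startle_gain = row$startle_gain, tau_startle = 10,
    kappa_social = row$kappa_social, kappa_cohesion = row$kappa_cohesion
  )
}

# per-sample speed multiplier: illumination gain x (1 + decaying startle)
speed_multiplier <- function(times, schedule, params) {
  if (is.null(schedule)) return(rep(1, length(times)))
  illum <- schedule_illumination_at(schedule, times)
  mult <- ifelse(illum == "dark", params$g_dark, 1)
  if (params$startle_gain > 0 && nrow(schedule$transitions)) {
    tt <- schedule$transitions$time_s
    last <- findInterval(times, tt)
    since <- ifelse(last >= 1, times - tt[pmax(last, 1)], Inf)
    mult <- mult * (1 + params$startle_gain * exp(-since / params$tau_startle))
  }
  mult
}

# deterministic per-fish draw sequence: 2 position draws, 1 heading draw,
# then the two noise vectors — identical for single-fish and group paths
draw_fish_noise <- function(seed, n_steps, arena) {
  set.seed(seed)
  if (arena$shape == "rectangle") {
    x0 <- runif(1, 0, arena$width)
    y0 <- runif(1, 0, arena$height)
  } else {
    r <- arena$diameter / 2 * sqrt(runif(1))
    a <- runif(1, 0, 2 * pi)
    x0 <- r * cos(a); y0 <- r * sin(a)
  }
  h0 <- runif(1, -pi, pi)
  list(x0 = x0, y0 = y0, h0 = h0,
       nv = rnorm(n_steps), nh = rnorm(n_steps))
}

arena_code <- function(arena) {
  if (arena$shape == "rectangle")
    list(type = 0L, bounds = c(0, arena$width, 0, arena$height))
  else
    list(type = 1L, bounds = c(arena$diameter / 2, 0, 0, 0))
}

#' Simulate one fish
#'
#' Runs the correlated random walk for a single fish. Identical
#' `(params, seed)` give bit-identical trajectories.
#'
#' @param params A [behavior_params()] (or [genotype_preset()]).
#' @param arena The arena to swim in.
#' @param schedule Optional [light_schedule()] driving dark-gain and startle
#'   modulation.
#' @param duration_s Recording length (s).
#' @param fps Frame rate (frames/s).
#' @param seed Integer seed; every random draw derives from it.
#' @param fish_id,genotype Metadata carried on the trajectory.
#' @param social Optional social drive: a list with `angle` (attraction
#'   bearing, rad) and `on` (logical/0-1 vector per frame, or a single value).
#' @return A [trajectory()] with all samples valid and inside the arena.
#' @export
simulate_fish <- function(params, arena, schedule = NULL, duration_s = 60,
                          fps = 25, seed = 1, fish_id = "fish1",
                          genotype = "WT", social = NULL) {
  stopifnot(inherits(params, "behavior_params"), inherits(arena, "arena"))
  if (duration_s <= 0 || fps <= 0) zt_abort("duration_s and fps must be > 0")
  n <- round(duration_s * fps)
  dt <- 1 / fps
  times <- (seq_len(n) - 1) * dt
  nz <- draw_fish_noise(seed, n - 1, arena)
  mult <- speed_multiplier(times[-1], schedule, params)
  if (is.null(social)) {
    social_angle <- 0; social_on <- rep(0, n - 1); ksoc <- 0
  } else {
    social_angle <- social$angle
    so <- social$on
    social_on <- if (length(so) == 1) rep(as.numeric(so), n - 1) else
      as.numeric(so)[-1]
    ksoc <- params$kappa_social
  }
  sigma_h <- sqrt(-2 * log(max(params$kappa_heading, 1e-12)))
  res <- crw_sim_cpp(matrix(nz$nv, ncol = 1), matrix(nz$nh, ncol = 1),
                     nz$x0, nz$y0, nz$h0, params$mu_speed * mult[1],
                     dt, params$mu_speed, params$sigma_speed, params$tau_speed,
                     sigma_h, params$kappa_wall, ksoc, social_angle,
                     social_on, mult, 0, arena_code(arena)$type,
                     arena_code(arena)$bounds)
  trajectory(fish_id,
             tibble::tibble(t = times, x = res$x[, 1], y = res$y[, 1],
                            valid = TRUE),
             fps = fps, arena = arena, genotype = genotype)
}

#' Simulate a social-preference trial
#'
#' Emulates the two social paradigms. For `paradigm = "juvenile"` the trial
#' is a 10-min baseline (opaque partitions in place: no social drive)
#' followed by a 10-min test period with the social turn bias active; for
#' `paradigm = "adult"` the social drive is on for the whole recording.
#'
#' @inheritParams simulate_fish
#' @param paradigm `"juvenile"` or `"adult"`.
#' @param preset Arena/partition preset as returned by
#'   [preset_juvenile_social()] / [preset_adult_social()].
#' @param baseline_s,test_s Period lengths (s).
#' @return A list with `trajectory`, `partition`, and a `periods` tibble
#'   (`period`, `start_s`, `end_s`).
#' @export
simulate_social_trial <- function(params, paradigm = c("juvenile", "adult"),
                                  preset = NULL, baseline_s = 600,
                                  test_s = 600, fps = 25, seed = 1,
                                  fish_id = "fish1", genotype = "WT") {
  paradigm <- match.arg(paradigm)
  if (is.null(preset)) {
    preset <- if (paradigm == "juvenile") preset_juvenile_social()
              else preset_adult_social()
  }
  if (paradigm == "juvenile") {
    duration <- baseline_s + test_s
    n <- round(duration * fps)
    on <- as.numeric(((seq_len(n) - 1) / fps) >= baseline_s)
    periods <- tibble::tibble(period = c("baseline", "test"),
                              start_s = c(0, baseline_s),
                              end_s = c(baseline_s, baseline_s + test_s))
  } else {
    duration <- test_s
    on <- 1
    periods <- tibble::tibble(period = "test", start_s = 0, end_s = test_s)
  }
  traj <- simulate_fish(params, preset$arena, schedule = NULL,
                        duration_s = duration, fps = fps, seed = seed,
                        fish_id = fish_id, genotype = genotype,
                        social = list(angle = preset$social_angle, on = on))
  list(trajectory = traj, partition = preset$partition, periods = periods)
}

#' Group recordings
#'
#' Bundles time-aligned trajectories recorded together in one arena.
#'
#' @param trajectories List of [trajectory()] objects sharing one arena and
#'   time base (same duration to within one frame).
#' @param paradigm One of `"open_field"`, `"light_dark"`, `"social_juvenile"`,
#'   `"social_adult"`, `"shoal"`.
#' @return A `group_recording` object.
#' @export
group_recording <- function(trajectories,
                            paradigm = c("shoal", "open_field", "light_dark",
                                         "social_juvenile", "social_adult")) {
  paradigm <- match.arg(paradigm)
  if (!length(trajectories) ||
      !all(vapply(trajectories, inherits, TRUE, "trajectory")))
    zt_abort("trajectories must be a list of trajectory objects")
  dur <- vapply(trajectories, traj_duration, 0)
  fps <- trajectories[[1]]$fps
  if (max(dur) - min(dur) > 1 / fps + 1e-9)
    zt_abort("member trajectories must have the same duration within one frame")
  if (paradigm == "shoal" && length(trajectories) < 2)
    zt_abort("shoal recordings require at least 2 fish")
  structure(list(trajectories = trajectories, paradigm = paradigm,
                 arena = trajectories[[1]]$arena),
            class = "group_recording")
}

#' Simulate a shoal
#'
#' Simulates `n_fish` coupled walkers: each fish follows [simulate_fish()]
#' dynamics plus a turn bias toward the centroid of the *other* fish, scaled
#' by `kappa_cohesion`. Per-fish random streams derive from `seed + i`
#' (i = 1..n_fish), so with `kappa_cohesion = 0` each fish reproduces the
#' independent simulation under the same seed exactly.
#'
#' @inheritParams simulate_fish
#' @param n_fish Number of fish (>= 2; the standard assay uses 6).
#' @return A [group_recording()] with paradigm `"shoal"`.
#' @export
simulate_shoal <- function(n_fish = 6, params, arena = preset_shoal_tank(),
                           duration_s = 300, fps = 25, seed = 1,
                           genotype = "WT") {
  stopifnot(inherits(params, "behavior_params"))
  if (n_fish < 2) zt_abort("a shoal needs at least 2 fish")
  n <- round(duration_s * fps)
  dt <- 1 / fps
  times <- (seq_len(n) - 1) * dt
  nz <- lapply(seq_len(n_fish), function(i) draw_fish_noise(seed + i, n - 1, arena))
  x0 <- vapply(nz, `[[`, 0, "x0"); y0 <- vapply(nz, `[[`, 0, "y0")
  if (anyDuplicated(cbind(x0, y0))) zt_abort("duplicate start positions")
  sigma_h <- sqrt(-2 * log(max(params$kappa_heading, 1e-12)))
  ac <- arena_code(arena)
  res <- crw_sim_cpp(
    vapply(nz, `[[`, numeric(n - 1), "nv"),
    vapply(nz, `[[`, numeric(n - 1), "nh"),
    x0, y0, vapply(nz, `[[`, 0, "h0"),
    rep(params$mu_speed, n_fish),
    dt, params$mu_speed, params$sigma_speed, params$tau_speed, sigma_h,
    params$kappa_wall, 0, 0, rep(0, n - 1), rep(1, n - 1),
    params$kappa_cohesion, ac$type, ac$bounds
  )
  trajs <- lapply(seq_len(n_fish), function(i) {
    trajectory(paste0("fish", i),
               tibble::tibble(t = times, x = res$x[, i], y = res$y[, i],
                              valid = TRUE),
               fps = fps, arena = arena, genotype = genotype)
  })
  group_recording(trajs, paradigm = "shoal")
}
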