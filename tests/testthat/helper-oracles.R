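# Independent brute-force oracles and fixture builders. These deliberately
# avoid the package's own geometry/accumulation code paths: everything here
# is a plain frame-by-frame (or pair-by-pair) loop over raw coordinates.

# random reflected walk built directly from clipped increments (no CRW model)
make_random_traj <- function(n_frames, arena, seed, fps = 25,
                             step_sd = 2, fish_id = "rnd", genotype = "WT") {
  set.seed(seed)
  if (arena$shape == "rectangle") {
    x <- numeric(n_frames); y <- numeric(n_frames)
    x[1] <- runif(1, 0, arena$width); y[1] <- runif(1, 0, arena$height)
    dx <- rnorm(n_frames - 1, 0, step_sd); dy <- rnorm(n_frames - 1, 0, step_sd)
    for (k in 2:n_frames) {
      x[k] <- min(max(x[k - 1] + dx[k - 1], 0), arena$width)
      y[k] <- min(max(y[k - 1] + dy[k - 1], 0), arena$height)
    }
  } else {
    r <- arena$diameter / 2
    x <- numeric(n_frames); y <- numeric(n_frames)
    repeat {
      x[1] <- runif(1, -r, r); y[1] <- runif(1, -r, r)
      if (x[1]^2 + y[1]^2 < r^2) break
    }
    dx <- rnorm(n_frames - 1, 0, step_sd); dy <- rnorm(n_frames - 1, 0, step_sd)
    for (k in 2:n_frames) {
      px <- x[k - 1] + dx[k - 1]; py <- y[k - 1] + dy[k - 1]
      rr <- sqrt(px^2 + py^2)
      if (rr > r) { px <- px * (r / rr) * 0.999; py <- py * (r / rr) * 0.999 }
      x[k] <- px; y[k] <- py
    }
  }
  trajectory(fish_id,
             tibble::tibble(t = (seq_len(n_frames) - 1) / fps, x = x, y = y,
                            valid = TRUE),
             fps = fps, arena = arena, genotype = genotype)
}

# hand-built trajectory from explicit sample vectors
make_traj <- function(t, x, y, arena, fps = 25, valid = TRUE,
                      fish_id = "fix", genotype = "WT") {
  trajectory(fish_id, tibble::tibble(t = t, x = x, y = y, valid = valid),
             fps = fps, arena = arena, genotype = genotype)
}

# a straight path with constant speed v (mm/s), arena long enough to never
# meet a wall; includes the closing frame so every bin holds a full
# complement of steps
constant_speed_traj <- function(v, duration_s, fps = 25) {
  n <- round(duration_s * fps) + 1
  width <- v * duration_s + 20
  x <- 5 + v * (0:(n - 1)) / fps
  make_traj((0:(n - 1)) / fps, x, rep(5, n), arena_rect(width, 10), fps = fps)
}

# juvenile-well path: 300 s in the conspecific sector, 100 s in the empty
# sector, 100 s in the neutral middle
dwell_fixture <- function(fps = 25) {
  jv <- preset_juvenile_social()
  n1 <- 300 * fps; n2 <- 100 * fps; n3 <- 100 * fps
  n <- n1 + n2 + n3
  y <- c(rep(8, n1), rep(-8, n2), rep(0, n3))
  make_traj((0:(n - 1)) / fps, rep(0, n), y, jv$arena, fps = fps)
}

oracle_path_length <- function(traj) {
  s <- traj$samples
  tot <- 0
  for (k in seq_len(nrow(s) - 1)) {
    if (s$valid[k] && s$valid[k + 1])
      tot <- tot + sqrt((s$x[k + 1] - s$x[k])^2 + (s$y[k + 1] - s$y[k])^2)
  }
  tot
}

oracle_binned <- function(traj, bin_s = 30) {
  s <- traj$samples
  n_bins <- floor(nrow(s) / traj$fps / bin_s + 1e-9)
  acc <- numeric(n_bins)
  for (k in seq_len(nrow(s) - 1)) {
    b <- floor((s$t[k] - s$t[1]) / bin_s) + 1
    if (b <= n_bins && s$valid[k] && s$valid[k + 1])
      acc[b] <- acc[b] + sqrt((s$x[k + 1] - s$x[k])^2 + (s$y[k + 1] - s$y[k])^2)
  }
  acc
}

# direct-geometry classifiers, one per preset partition (independent of the
# package's zone code); return a zone name or NA per point
oracle_classify_open_field <- function(x, y, side = 300) {
  s <- side / sqrt(2); lo <- (side - s) / 2; hi <- lo + s
  ifelse(x >= lo & x <= hi & y >= lo & y <= hi, "center", "periphery")
}

oracle_classify_juvenile <- function(x, y, diameter = 22) {
  r <- diameter / 2
  inside <- x^2 + y^2 <= r^2
  ifelse(inside & y >= r / 2, "conspecific",
         ifelse(inside & y <= -r / 2, "empty", NA_character_))
}

oracle_classify_adult <- function(x, y, width = 105) {
  ifelse(x <= width / 2, "conspecific", "empty")
}

# frame-loop dwell time and distance per zone given a classifier function
oracle_zone_occupancy <- function(traj, classify) {
  s <- traj$samples
  dt <- 1 / traj$fps
  zones <- list()
  for (k in seq_len(nrow(s))) {
    if (!s$valid[k]) next
    z <- classify(s$x[k], s$y[k])
    if (is.na(z)) next
    if (is.null(zones[[z]])) zones[[z]] <- c(time = 0, dist = 0)
    zones[[z]]["time"] <- zones[[z]]["time"] + dt
    if (k < nrow(s) && s$valid[k + 1]) {
      zones[[z]]["dist"] <- zones[[z]]["dist"] +
        sqrt((s$x[k + 1] - s$x[k])^2 + (s$y[k + 1] - s$y[k])^2)
    }
  }
  zones
}

oracle_mean_iid <- function(group) {
  trajs <- group$trajectories
  n <- length(trajs)
  nf <- nrow(trajs[[1]]$samples)
  per_frame <- numeric(0)
  for (k in seq_len(nf)) {
    ds <- c()
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      if (trajs[[i]]$samples$valid[k] && trajs[[j]]$samples$valid[k]) {
        ds <- c(ds, sqrt((trajs[[i]]$samples$x[k] - trajs[[j]]$samples$x[k])^2 +
                         (trajs[[i]]$samples$y[k] - trajs[[j]]$samples$y[k])^2))
      }
    }
    if (length(ds)) per_frame <- c(per_frame, mean(ds))
  }
  mean(per_frame)
}
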