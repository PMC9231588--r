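test_that("zone membership handles interior, corner and boundary points", {
  of <- preset_open_field()
  expect_true(point_in_zone(150, 150, of$partition, "center"))
  expect_false(point_in_zone(150, 150, of$partition, "periphery"))
  expect_false(point_in_zone(0, 0, of$partition, "center"))
  expect_true(point_in_zone(0, 0, of$partition, "periphery"))
  # boundary tie-break: a point on the center-zone edge belongs to center
  # (first-listed zone)
  s <- 300 / sqrt(2); lo <- (300 - s) / 2
  expect_true(point_in_zone(lo, 150, of$partition, "center"))
  expect_false(point_in_zone(lo, 150, of$partition, "periphery"))
  expect_error(point_in_zone(1, 1, of$partition, "nave"),
               class = "zebratrax_unknown_zone")
  expect_error(point_in_zone(-5, 150, of$partition, "center"),
               class = "zebratrax_out_of_arena")
})

test_that("polygon containment agrees with an independent implementation on 1000 random points", {
  skip_if_not_installed("mgcv")
  set.seed(71)
  # irregular pentagon inside a 100x100 arena
  vx <- c(10, 80, 95, 50, 15)
  vy <- c(10, 5, 60, 92, 70)
  arena <- arena_rect(100, 100)
  part <- arena_partition(arena, list(zone_polygon("pent", vx, vy)))
  px <- runif(1000, 0, 100); py <- runif(1000, 0, 100)
  got <- point_in_zone(px, py, part, "pent")
  ref <- as.logical(mgcv::in.out(cbind(c(vx, vx[1]), c(vy, vy[1])),
                                 cbind(px, py)))
  expect_identical(got, ref)
})

test_that("circular band sectors agree with direct inequalities on random points", {
  jv <- preset_juvenile_social()
  set.seed(72)
  r <- 11
  px <- runif(1000, -r, r); py <- runif(1000, -r, r)
  keep <- px^2 + py^2 < r^2
  got <- classify_points(px[keep], py[keep], jv$partition)
  ref <- oracle_classify_juvenile(px[keep], py[keep])
  expect_identical(got, ref)
})

test_that("trajectory validation enforces time order, sampling and bounds", {
  arena <- arena_rect(100, 100)
  good <- tibble::tibble(t = (0:9) / 25, x = seq(1, 10), y = rep(5, 10))
  expect_s3_class(trajectory("f1", good, 25, arena), "trajectory")
  bad_t <- good; bad_t$t[5] <- bad_t$t[3]
  expect_error(trajectory("f9", bad_t, 25, arena),
               class = "zebratrax_nonmonotone_time")
  expect_error(trajectory("f9", bad_t, 25, arena), "f9")
  oob <- good; oob$x[4] <- 250
  expect_error(trajectory("f1", oob, 25, arena),
               class = "zebratrax_out_of_arena")
  expect_error(trajectory("f1", good, 50, arena), "sampling interval")
})

test_that("path_length matches closed forms and a loop oracle", {
  arena <- arena_rect(100, 100)
  still <- make_traj(c(0, 0.04, 0.08), rep(5, 3), rep(5, 3), arena)
  expect_equal(path_length(still), 0)
  tri <- make_traj(c(0, 0.04), c(0, 3), c(0, 4), arena)
  expect_equal(path_length(tri), 5)
  rnd <- make_random_traj(101, arena, seed = 5)
  expect_equal(path_length(rnd), oracle_path_length(rnd), tolerance = 1e-12)
  none <- make_traj(c(0, 0.04), c(1, 2), c(1, 2), arena,
                    valid = c(FALSE, FALSE))
  expect_error(path_length(none), "no valid samples")
})

test_that("binned distances are conservative and match a frame-loop oracle", {
  arena <- arena_rect(2000, 10)
  # constant 1 mm/s along x for 3 minutes (include the closing frame so each
  # bin holds a full complement of steps)
  n <- 180 * 25 + 1
  tr <- make_traj((0:(n - 1)) / 25, (0:(n - 1)) / 25, rep(5, n), arena)
  b <- binned_distance(tr)
  expect_equal(nrow(b), 6)
  expect_equal(b$distance_mm, rep(30, 6), tolerance = 1e-9)
  # a 45-min recording yields exactly 90 complete 30-s bins
  big <- simulate_fish(genotype_preset("WT", "larva"), preset_larval_well(),
                       duration_s = 2700, seed = 11)
  bb <- binned_distance(big)
  expect_equal(nrow(bb), 90)
  expect_equal(sum(bb$distance_mm), path_length(big), tolerance = 1e-9)
  rnd <- make_random_traj(25 * 90, arena_rect(100, 100), seed = 6)
  expect_equal(binned_distance(rnd)$distance_mm, oracle_binned(rnd),
               tolerance = 1e-9)
  short <- make_traj(c(0, 0.04), c(0, 1), c(0, 1), arena_rect(10, 10))
  expect_error(binned_distance(short), "shorter than one bin")
})

test_that("zone occupancy conserves time under a covering partition and matches the frame loop", {
  of <- preset_open_field()
  rnd <- make_random_traj(2500, of$arena, seed = 7, step_sd = 15)
  occ <- zone_occupancy(rnd, of$partition)
  expect_equal(sum(occ$time_s), 2500 / 25, tolerance = 1e-9)
  ref <- oracle_zone_occupancy(rnd, oracle_classify_open_field)
  for (z in names(ref)) {
    expect_equal(occ$time_s[occ$zone == z], unname(ref[[z]]["time"]),
                 tolerance = 1e-9)
    expect_equal(occ$distance_mm[occ$zone == z], unname(ref[[z]]["dist"]),
                 tolerance = 1e-9)
  }
  # trajectory confined to one zone gets all the time
  mid <- make_traj((0:99) / 25, rep(150, 100), rep(150, 100), of$arena)
  occ2 <- zone_occupancy(mid, of$partition)
  expect_equal(occ2$time_s[occ2$zone == "center"], 4)
  expect_equal(occ2$time_s[occ2$zone == "periphery"], 0)
  expect_error(zone_occupancy(rnd, of$partition, window = c(5, 5)),
               "empty window")
})

test_that("epoch segmentation partitions the scheduled span", {
  sched <- preset_larval_schedule()
  expect_equal(sched$epochs$label,
               c("baseline", "L0", "D1", "L1", "D2", "L2", "D3", "L3"))
  expect_equal(sched$transitions$time_s, c(900, 1200, 1500, 1800, 2100, 2400))
  expect_equal(sched$transitions$direction,
               rep(c("light_to_dark", "dark_to_light"), 3))
  dark <- sched$epochs[sched$epochs$illumination == "dark", ]
  expect_equal(nrow(dark), 3)
  expect_true(all(dark$end_s - dark$start_s == 300))

  tr <- simulate_fish(genotype_preset("WT", "larva"), preset_larval_well(),
                      schedule = sched, duration_s = 2700, seed = 3)
  slices <- segment_epochs(tr, sched)
  expect_named(slices, sched$epochs$label)
  n_each <- vapply(slices, function(s) nrow(s$samples), 0L)
  expect_equal(sum(n_each), nrow(tr$samples))
  # concatenating the slices reproduces the trajectory sample-for-sample
  recon <- do.call(rbind, lapply(slices, function(s) s$samples))
  expect_equal(recon$t, tr$samples$t)
  expect_equal(recon$x, tr$samples$x)

  expect_error(light_schedule(tibble::tibble(label = character(),
                                             start_s = numeric(),
                                             end_s = numeric(),
                                             illumination = character())),
               "no epochs")
  short <- make_traj((0:49) / 25, rep(1, 50), rep(1, 50), arena_rect(10, 10))
  expect_error(segment_epochs(short, sched), "longer than recording")
})

test_that("short dropouts are bridged, long ones stay excluded", {
  arena <- arena_rect(2000, 10)
  n <- 100
  valid <- rep(TRUE, n)
  valid[40:45] <- FALSE            # 0.24 s gap -> bridged
  tr <- make_traj((0:(n - 1)) / 25, (0:(n - 1)), rep(5, n), arena,
                  valid = valid)
  fixed <- interpolate_dropouts(tr)
  expect_true(all(fixed$samples$valid))
  # interpolation is exact for a linear path
  expect_equal(fixed$samples$x[40:45], 39:44)
  valid2 <- rep(TRUE, n)
  valid2[30:60] <- FALSE           # 1.24 s gap -> kept invalid
  tr2 <- make_traj((0:(n - 1)) / 25, (0:(n - 1)), rep(5, n), arena,
                   valid = valid2)
  fixed2 <- interpolate_dropouts(tr2)
  expect_equal(sum(!fixed2$samples$valid), 31)
  expect_lt(path_length(fixed2), path_length(fixed))
})
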