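test_that("simulation is seeded, bounded, and degenerates to a stationary fish", {
  arena <- preset_open_field()$arena
  p0 <- behavior_params(mu_speed = 0, sigma_speed = 0)
  tr <- simulate_fish(p0, arena, duration_s = 10, seed = 4)
  expect_equal(path_length(tr), 0)
  expect_equal(length(unique(tr$samples$x)), 1)

  p <- genotype_preset("WT", "adult")
  a <- simulate_fish(p, arena, duration_s = 30, seed = 9)
  b <- simulate_fish(p, arena, duration_s = 30, seed = 9)
  expect_identical(a$samples, b$samples)
  c_ <- simulate_fish(p, arena, duration_s = 30, seed = 10)
  expect_false(identical(a$samples, c_$samples))

  # reflective walls never overshoot, even under strong wall attraction
  pw <- behavior_params(mu_speed = 20, sigma_speed = 8, kappa_wall = 3)
  trw <- simulate_fish(pw, arena_rect(50, 50), duration_s = 60, seed = 2)
  expect_true(all(trw$samples$x >= 0 & trw$samples$x <= 50))
  expect_true(all(trw$samples$y >= 0 & trw$samples$y <= 50))
  well <- preset_larval_well()
  trc <- simulate_fish(pw, well, duration_s = 60, seed = 2)
  expect_true(all(trc$samples$x^2 + trc$samples$y^2 <= (well$diameter / 2)^2 + 1e-9))

  expect_error(behavior_params(mu_speed = NaN), "finite")
  expect_error(behavior_params(mu_speed = -1), "out of range")
})

test_that("realized speed tracks mu_speed and the dark gain", {
  # low-noise calibration: mean realized speed within 10% of mu over 20 seeds
  p <- behavior_params(mu_speed = 5, sigma_speed = 0.25, kappa_heading = 0.98)
  arena <- arena_rect(500, 500)
  sp <- vapply(1:20, function(s) {
    tr <- simulate_fish(p, arena, duration_s = 120, seed = s)
    path_length(tr) / 120
  }, 0)
  expect_lt(abs(mean(sp) - 5) / 5, 0.10)

  # dark/light epoch speed ratio recovers g_dark within 10% when startle = 0
  sched <- preset_larval_schedule()
  pg <- behavior_params(mu_speed = 2.7, sigma_speed = 0.9, g_dark = 2,
                        startle_gain = 0)
  rat <- vapply(1:20, function(s) {
    tr <- simulate_fish(pg, arena_rect(100, 100), schedule = sched,
                        duration_s = 2700, seed = s)
    em <- epoch_mean_activity(tr, sched)
    dk <- em$mean_mm_per_bin[em$illumination == "dark"]
    lt <- em$mean_mm_per_bin[em$epoch %in% c("L1", "L2", "L3")]
    mean(dk) / mean(lt)
  }, 0)
  expect_lt(abs(mean(rat) - 2) / 2, 0.10)
})

test_that("genotype presets encode the reported effect directions", {
  for (stage in c("larva", "adult")) {
    wt <- genotype_preset("WT", stage)
    het <- genotype_preset("HET", stage)
    hom <- genotype_preset("HOM", stage)
    expect_lt(hom$mu_speed, wt$mu_speed)
    expect_gt(hom$kappa_wall, wt$kappa_wall)
    expect_gt(hom$startle_gain, wt$startle_gain)
    expect_lt(hom$kappa_social, wt$kappa_social)
    expect_lt(hom$kappa_cohesion, wt$kappa_cohesion)
    # heterozygotes sit between (or equal to) the homozygous lines
    expect_true(het$mu_speed <= wt$mu_speed && het$mu_speed >= hom$mu_speed)
    expect_true(het$kappa_social <= wt$kappa_social &&
                  het$kappa_social >= hom$kappa_social)
  }
})

test_that("social trials are symmetric without attraction and biased with it", {
  p0 <- behavior_params(mu_speed = 5.17, sigma_speed = 1.8, kappa_social = 0)
  s0 <- vapply(1:50, function(s) {
    tr <- simulate_social_trial(p0, "juvenile", baseline_s = 120,
                                test_s = 240, seed = s)
    spi(tr$trajectory, tr$partition, window = c(120, 360))$spi
  }, 0)
  expect_lt(abs(mean(s0)), 0.1)

  pb <- behavior_params(mu_speed = 5.17, sigma_speed = 1.8, kappa_social = 0.8)
  sb <- vapply(1:50, function(s) {
    tr <- simulate_social_trial(pb, "juvenile", baseline_s = 120,
                                test_s = 240, seed = s)
    spi(tr$trajectory, tr$partition, window = c(120, 360))$spi
  }, 0)
  expect_gte(sum(sb > 0), 45)
  # same seed reproducibility
  t1 <- simulate_social_trial(pb, "juvenile", seed = 7)
  t2 <- simulate_social_trial(pb, "juvenile", seed = 7)
  expect_identical(t1$trajectory$samples, t2$trajectory$samples)
})

test_that("uncoupled shoals reproduce independent walks; cohesion tightens them monotonically", {
  p0 <- behavior_params(mu_speed = 5, sigma_speed = 1.5, kappa_cohesion = 0)
  sh <- simulate_shoal(4, p0, duration_s = 30, seed = 100)
  for (i in 1:4) {
    ind <- simulate_fish(p0, preset_shoal_tank(), duration_s = 30,
                         seed = 100 + i)
    expect_identical(sh$trajectories[[i]]$samples$x, ind$samples$x)
    expect_identical(sh$trajectories[[i]]$samples$y, ind$samples$y)
  }

  kc_grid <- c(0, 0.15, 0.45, 1.2)
  mean_iid <- vapply(kc_grid, function(kc) {
    p <- behavior_params(mu_speed = 5, sigma_speed = 1.5, kappa_cohesion = kc)
    mean(vapply(1:30, function(s) {
      shoaling_iid(simulate_shoal(6, p, duration_s = 120,
                                  seed = 5000 + s * 37))$mean_iid
    }, 0))
  }, 0)
  expect_true(all(diff(mean_iid) < 0))

  sh1 <- simulate_shoal(6, p0, duration_s = 10, seed = 8)
  sh2 <- simulate_shoal(6, p0, duration_s = 10, seed = 8)
  expect_identical(sh1$trajectories[[3]]$samples, sh2$trajectories[[3]]$samples)
  expect_error(simulate_shoal(1, p0), "at least 2 fish")
})
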