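#!/usr/bin/env Rscript

# Step 2 — read the tracking tables written by 01_simulate.R and compute the
# per-fish behavioral metrics of each paradigm:
#   light/dark:  mean activity (mm per 30 s, first 15 min) and the
#                after/before speed ratio at lights-off and lights-on
#   open field:  mean activity and thigmotaxis time/distance ratios
#   social:      SPI per period (juvenile) or per mode (adult)
#   shoal:       mean inter-individual distance per group
#
# Output: results/metrics/<paradigm>.csv

suppressMessages({ library(zebratrax); library(dplyr); library(purrr) })

trk <- "results/tracking"
out <- "results/metrics"
dir.create(out, showWarnings = FALSE, recursive = TRUE)
stopifnot(dir.exists(trk))

message("Light/dark metrics")
sched <- preset_larval_schedule()
larvae <- read_tracking(file.path(trk, "light_dark.csv"),
                        arena = preset_larval_well())
ld <- map_dfr(larvae, function(tr) {
  ap <- activity_profile(tr, window = c(0, 900))
  tibble(fish_id = tr$fish_id, genotype = tr$genotype,
         mean_activity = ap$mean_activity,
         ratio_light_to_dark = transition_response(tr, sched,
                                                   "light_to_dark")$mean_ratio,
         ratio_dark_to_light = transition_response(tr, sched,
                                                   "dark_to_light")$mean_ratio)
})
readr::write_csv(ld, file.path(out, "light_dark.csv"))
message("  ", nrow(ld), " fish")

message("Open-field metrics")
of <- preset_open_field()
adults <- read_tracking(file.path(trk, "open_field.csv"), arena = of$arena)
opf <- map_dfr(adults, function(tr) {
  th <- thigmotaxis(tr, partition = of$partition)
  tibble(fish_id = tr$fish_id, genotype = tr$genotype,
         mean_activity = activity_profile(tr)$mean_activity,
         thigmo_time = th$time_ratio, thigmo_distance = th$distance_ratio)
})
readr::write_csv(opf, file.path(out, "open_field.csv"))
message("  ", nrow(opf), " fish")

message("Juvenile social metrics (10-min baseline, 10-min test)")
jv <- preset_juvenile_social()
juv <- read_tracking(file.path(trk, "social_juvenile.csv"), arena = jv$arena)
sj <- map_dfr(juv, function(tr) {
  sb <- spi(tr, jv$partition, window = c(0, 600), period = "baseline")
  st <- spi(tr, jv$partition, window = c(600, 1200), period = "test")
  tibble(fish_id = tr$fish_id, genotype = tr$genotype,
         spi_baseline = sb$spi, spi_test = st$spi,
         delta_spi = delta_spi(sb, st))
})
readr::write_csv(sj, file.path(out, "social_juvenile.csv"))
message("  ", nrow(sj), " fish")

message("Adult social metrics")
ad <- preset_adult_social()
ads <- read_tracking(file.path(trk, "social_adult.csv"), arena = ad$arena)
sa <- map_dfr(ads, function(tr) {
  tibble(fish_id = tr$fish_id, genotype = tr$genotype,
         spi_time = spi(tr, ad$partition, mode = "time")$spi,
         spi_distance = spi(tr, ad$partition, mode = "distance")$spi)
})
readr::write_csv(sa, file.path(out, "social_adult.csv"))
message("  ", nrow(sa), " fish")

message("Shoaling metrics")
tank <- preset_shoal_tank()
shoal_files <- list.files(trk, pattern = "^shoal_", full.names = TRUE)
sh <- map_dfr(shoal_files, function(f) {
  trajs <- read_tracking(f, arena = tank)
  grp <- group_recording(unname(trajs), paradigm = "shoal")
  tibble(group_id = sub("\\.csv$", "", basename(f)),
         genotype = trajs[[1]]$genotype,
         mean_iid = shoaling_iid(grp)$mean_iid)
})
readr::write_csv(sh, file.path(out, "shoal.csv"))
message("  ", nrow(sh), " shoals")
message("Done: per-fish metric tables under ", out)
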