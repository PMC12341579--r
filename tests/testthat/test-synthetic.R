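test_that("generator is deterministic under equal seeds", {
  cfg <- quick_config(cluster_specs = cluster_layout(1, 1), gaussian_sd = 3,
                      cluster_jitter_speed_um_min = 0.05, seed = 11)
  m1 <- simulate_ring_movie(cfg)
  m2 <- simulate_ring_movie(cfg)
  expect_identical(m1$frames, m2$frames)
  expect_identical(m1$truth, m2$truth)
  co1 <- simulate_cohort(10, target_r = 0.8, seed = 4)
  co2 <- simulate_cohort(10, target_r = 0.8, seed = 4)
  expect_identical(co1, co2)
})

test_that("config invariants are enforced", {
  expect_error(sim_config(ring_diameter0_um = 80, image_size_px = c(96, 96),
                          pixel_size_um = 0.4), "field of view")
  expect_error(sim_config(junction_angles_rad = c(1, 1)), "overlap")
  expect_error(sim_config(cable_enrichment = 0.5), "cable_enrichment")
  expect_error(
    sim_config(cluster_specs = cluster_spec("radial", 0, sigma_um = -1)),
    "sigma")
})

test_that("clusterless noiseless ring is rotationally symmetric", {
  mov <- simulate_ring_movie(quick_config(n_frames = 1L))
  g <- mov$truth$geometry[1, ]
  prof <- unwrap_ring(mov$frames[, , 1], g, mov$config$pixel_size_um)
  expect_lt(stats::sd(prof$intensity) / mean(prof$intensity), 0.01)
})

test_that("stalled ring has constant truth radius; closing ring nonincreasing", {
  mov <- simulate_ring_movie(quick_config(n_frames = 5L))
  expect_equal(diff(range(mov$truth$geometry$radius_um)), 0)
  mov2 <- simulate_ring_movie(quick_config(closure_velocity_um_per_min = 0.3,
                                           n_frames = 20L))
  expect_true(all(diff(mov2$truth$geometry$radius_um) <= 0))
})

test_that("tangential truth arc displacement follows speed * time", {
  # 0.2 um/min for 60 one-minute steps on a stalled 50 um ring -> 12 um
  cfg <- sim_config(cluster_specs = cluster_spec("tangential", 0,
                                                 speed_um_min = 0.2),
                    closure_velocity_um_per_min = 0,
                    junction_angles_rad = numeric(0),
                    cluster_jitter_speed_um_min = 0,
                    n_frames = 61L, gaussian_sd = 0)
  mov <- simulate_ring_movie(cfg)
  tr <- mov$truth$clusters
  R <- mov$truth$geometry$radius_um[1]
  disp <- R * abs(tr$angle_rad[tr$frame == 61] - tr$angle_rad[tr$frame == 1])
  expect_equal(disp, 12, tolerance = 1e-8)
})

test_that("clusters reflect at junctions instead of crossing them", {
  cfg <- quick_config(cluster_specs = cluster_spec("tangential", 1.2,
                                                   speed_um_min = 1),
                      junction_angles_rad = c(0.8, 2.5),
                      n_frames = 30L)
  mov <- simulate_ring_movie(cfg)
  th <- mov$truth$clusters$angle_rad
  # stays inside the (0.8, 2.5) segment at all times
  expect_true(all(th > 0.8 - 1e-9 & th < 2.5 + 1e-9))
})

test_that("adding a cluster conserves the expected integrated intensity", {
  base <- simulate_ring_movie(quick_config(n_frames = 1L))
  amp <- 200
  sig <- 0.5
  withc <- simulate_ring_movie(quick_config(
    n_frames = 1L,
    cluster_specs = cluster_spec("radial", pi / 3, amplitude = amp,
                                 sigma_um = sig)))
  added <- sum(withc$frames) - sum(base$frames)
  expected <- amp * 2 * pi * (sig / withc$config$pixel_size_um)^2
  expect_equal(added, expected, tolerance = 0.01)
})

test_that("rendering then measuring recovers ground-truth cluster angles", {
  cfg <- quick_config(cluster_specs = cluster_layout(2, 2), n_frames = 1L)
  mov <- simulate_ring_movie(cfg)
  res <- run_cluster_pipeline(mov)
  truth <- sort(mov$truth$clusters$angle_rad[mov$truth$clusters$frame == 1])
  est <- sort(res$det$angle_rad)
  expect_equal(length(est), 4L)
  R <- mov$truth$geometry$radius_um[1]
  arc_err <- R * abs(woundring:::angle_diff(est, truth))
  expect_lt(max(arc_err), 0.5 * cfg$pixel_size_um)
})

test_that("retraction trace follows the closed-form recoil model", {
  tr <- simulate_retraction_trace(1, 1, times_s = c(0, 0.5, 1))
  expect_equal(tr$length_um[1], 0)
  expect_equal(tr$length_um[3], 1 - exp(-1), tolerance = 1e-12)
  # plateau (T0/zeta) * tau
  tr2 <- simulate_retraction_trace(6.2, 5, times_s = c(0, 1, 500))
  expect_equal(tr2$length_um[3], 31, tolerance = 1e-6)
  expect_error(simulate_retraction_trace(1, 1, noise_sd_um = -1), "noise")
  expect_error(simulate_retraction_trace(1, -2), "tau")
})

test_that("cohort generator hits requested correlation structure", {
  co <- simulate_cohort(50, slope = 0.2, noise_sd = 0, seed = 1)
  expect_equal(pearson_r(co$radial_fraction, co$closure_velocity_um_min), 1)
  co0 <- simulate_cohort(10000, slope = 0, noise_sd = 0.05, seed = 2)
  expect_lt(abs(pearson_r(co0$radial_fraction, co0$closure_velocity_um_min)),
            0.05)
  cot <- simulate_cohort(10000, target_r = 0.8, seed = 3)
  expect_equal(pearson_r(cot$radial_fraction, cot$closure_velocity_um_min),
               0.8, tolerance = 0.025)
  expect_error(simulate_cohort(10, target_r = 1.2), "target_r")
  expect_error(simulate_cohort(10), "exactly one")
  expect_error(simulate_cohort(2, noise_sd = 0), "n")
})

test_that("burst series carries the configured RhoA-to-myosin lag", {
  b0 <- simulate_burst_series(lag_min = 0, snr = Inf)
  expect_equal(attr(b0, "rhoa_peak_min"), attr(b0, "myosin_peak_min"))
  b4 <- simulate_burst_series(lag_min = 4, dt_min = 1, snr = Inf)
  expect_equal(attr(b4, "myosin_peak_min") - attr(b4, "rhoa_peak_min"), 4)
  expect_error(simulate_burst_series(lag_min = 25, duration_min = 30),
               "beyond")
  expect_error(simulate_burst_series(lag_min = -1), "lag_min")
})

test_that("movie TIFF + sidecar roundtrip preserves data and calibration", {
  mov <- simulate_ring_movie(quick_config(n_frames = 3L, gaussian_sd = 2))
  dir <- withr::local_tempdir()
  paths <- write_movie(mov, dir, "test")
  back <- read_movie(paths[["tif"]])
  expect_equal(dim(back$frames), dim(mov$frames))
  # 32-bit float storage: relative error bounded by single precision
  expect_lt(max(abs(back$frames - mov$frames)) / max(mov$frames), 1e-6)
  expect_equal(back$meta$pixel_size_um, mov$config$pixel_size_um)
  expect_equal(back$meta$truth$closure_time_min, NULL)
})
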