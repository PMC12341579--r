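test_that("ratio map handles trivial and masked cases", {
  a <- matrix(100, 20, 20)
  expect_equal(ratio_map(a, a), matrix(1, 20, 20))
  expect_equal(ratio_map(2 * a, a), matrix(2, 20, 20))
  expect_error(ratio_map(a, matrix(1, 10, 10)), "shape")
  # invariance under common rescaling of both channels
  d <- matrix(stats::runif(400, 50, 150), 20, 20)
  expect_equal(ratio_map(3 * d, 3 * a), ratio_map(d, a))
  # low-acceptor pixels masked
  a2 <- a
  a2[1, 1] <- 0.01
  r <- ratio_map(d, a2, floor = 50)
  expect_true(is.na(r[1, 1]))
})

test_that("cable ratio elevation matches the generator gain", {
  cfg <- sim_config(n_frames = 20L, closure_velocity_um_per_min = 0,
                    gaussian_sd = 0, seed = 2)
  fm <- simulate_fret_sequence(cfg, ablation_frame = 2L, lag_min = 4,
                               rhoa_gain = 1.8)
  # frame 1 is pre-ablation: no burst modulation
  r <- ratio_map(fm$donor[, , 1], fm$acceptor[, , 1])
  g <- fm$truth$geometry[1, ]
  prof <- unwrap_ring(r, g, cfg$pixel_size_um)
  expect_equal(mean(prof$ridge_intensity), 1.8, tolerance = 0.05)
})

test_that("ring sections tile the perimeter and normalize to 1", {
  geom <- tibble::tibble(frame = 1L, cx_um = 28.8, cy_um = 28.8,
                         radius_um = 25)
  u <- matrix(100, 288, 288)
  s <- section_ring(u, u, geom, pixel_size_um = 0.2)
  expect_equal(nrow(s), 157L) # floor(2 pi 25)
  expect_equal(s$myosin_density_norm, rep(1, 157))
  expect_equal(s$rhoa_activity_norm, rep(1, 157))
  expect_error(section_ring(u, u, tibble::tibble(frame = 1, cx_um = 1,
                                                 cy_um = 1, radius_um = 0.1),
                            0.2), "shorter")
})

test_that("per-frame normalized section means average to one", {
  cfg <- quick_config(cluster_specs = cluster_layout(1, 1), n_frames = 1L,
                      gaussian_sd = 3, seed = 4)
  mov <- simulate_ring_movie(cfg)
  g <- mov$truth$geometry[1, ]
  g$frame <- 1L
  s <- section_ring(mov$frames[, , 1], mov$frames[, , 1], g,
                    cfg$pixel_size_um)
  expect_equal(mean(s$myosin_density_norm), 1, tolerance = 0.01)
  expect_equal(mean(s$rhoa_activity_norm), 1, tolerance = 0.01)
})

test_that("sections on clusters are labelled and denser than the cable", {
  cfg <- quick_config(cluster_specs = cluster_layout(1, 1), n_frames = 10L)
  mov <- simulate_ring_movie(cfg)
  res <- run_cluster_pipeline(mov)
  g <- res$ds[1, ]
  s <- section_ring(mov$frames[, , 1], mov$frames[, , 1], g,
                    cfg$pixel_size_um, tracks = res$classified)
  expect_setequal(unique(s$label), c("cable", "radial", "tangential"))
  expect_gt(min(s$myosin_density_norm[s$label != "cable"]),
            mean(s$myosin_density_norm[s$label == "cable"]))
})

test_that("activity-density curve saturates and compares labels fairly", {
  # synthetic sections: RhoA rises with density then plateaus
  set.seed(5)
  n <- 400
  dens <- stats::runif(n, 0.5, 2.5)
  rhoa <- pmin(dens, 1.3) / 1.3 + stats::rnorm(n, sd = 0.03)
  sec <- tibble::tibble(
    frame = 1L, section = seq_len(n), angle_rad = 0, arc_center_um = 0,
    myosin_density_norm = dens, rhoa_activity_norm = rhoa,
    label = sample(c("radial", "tangential", "cable"), n, replace = TRUE))
  av <- activity_vs_density(sec, n_bins = 6L)
  expect_lt(av$curve$mean_rhoa[1], av$curve$mean_rhoa[3])
  late <- av$curve$mean_rhoa[5:6]
  expect_lt(abs(diff(late)), 0.05)
  # equal RhoA on both cluster classes (same generative law):
  bl <- av$by_label
  d <- abs(bl$mean_rhoa[bl$label == "radial"] -
             bl$mean_rhoa[bl$label == "tangential"])
  pooled_se <- sqrt(sum(bl$se_rhoa[bl$label != "cable"]^2))
  expect_lt(d, 2 * pooled_se)
  expect_error(activity_vs_density(sec[1:10, ]), "20")
})

test_that("constant activity yields flat unit bins", {
  sec <- tibble::tibble(
    frame = 1L, section = 1:40, angle_rad = 0, arc_center_um = 0,
    myosin_density_norm = seq(0.5, 1.5, length.out = 40),
    rhoa_activity_norm = 1, label = "cable")
  av <- suppressMessages(activity_vs_density(sec, n_bins = 4L))
  expect_equal(av$curve$mean_rhoa, rep(1, 4))
})

test_that("peak lag is antisymmetric and exact on clean series", {
  b <- simulate_burst_series(lag_min = 0, snr = Inf)
  same <- peak_lag(tibble::tibble(time_min = b$time_min, rhoa = b$rhoa,
                                  myosin = b$rhoa))
  expect_equal(same$lag_min, 0)
  b4 <- simulate_burst_series(lag_min = 4, snr = Inf)
  pl <- peak_lag(b4)
  expect_equal(pl$lag_min, 4, tolerance = 0.3)
  flipped <- peak_lag(tibble::tibble(time_min = b4$time_min,
                                     rhoa = b4$myosin, myosin = b4$rhoa))
  expect_equal(flipped$lag_min, -pl$lag_min, tolerance = 1e-9)
})

test_that("boundary peaks are flagged unreliable", {
  d <- tibble::tibble(time_min = 0:10, rhoa = 10:0, myosin = 0:10)
  expect_warning(pl <- peak_lag(d), "boundary")
  expect_false(pl$reliable)
})

test_that("lag recovered from a rendered FRET movie", {
  cfg <- sim_config(image_size_px = c(144L, 144L), ring_diameter0_um = 20,
                    closure_velocity_um_per_min = 0, n_frames = 26L,
                    gaussian_sd = 2, seed = 12)
  fm <- simulate_fret_sequence(cfg, ablation_frame = 2L, lag_min = 4,
                               rise_min = 7)
  series <- purrr::map_dfr(seq_len(cfg$n_frames), function(t) {
    g <- fm$truth$geometry[t, ]
    r <- ratio_map(fm$donor[, , t], fm$acceptor[, , t])
    pr <- woundring:::unwrap_profiles(r, g, cfg$pixel_size_um, 1)
    pm <- woundring:::unwrap_profiles(fm$myosin[, , t], g,
                                      cfg$pixel_size_um, 1)
    tibble::tibble(time_min = g$time_min,
                   rhoa = mean(pr$ridge, na.rm = TRUE),
                   myosin = mean(pm$ridge, na.rm = TRUE))
  })
  pl <- peak_lag(series)
  expect_equal(pl$lag_min, 4, tolerance = 1)
  expect_equal(pl$myosin_peak_min, fm$truth$myosin_peak_min, tolerance = 1)
})
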