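test_that("detector finds each rendered cluster once, none on blank rings", {
  cfg <- quick_config(cluster_specs = cluster_layout(2, 2), n_frames = 1L)
  mov <- simulate_ring_movie(cfg)
  res <- run_cluster_pipeline(mov)
  expect_equal(nrow(res$det), 4L)
  blank <- run_cluster_pipeline(simulate_ring_movie(
    quick_config(n_frames = 3L, gaussian_sd = 3, seed = 2)))
  expect_equal(nrow(blank$det), 0L)
})

test_that("detected spacing matches the rendered ~10 um cluster spacing", {
  sp <- vapply(1:3, function(s) {
    n <- 7L # 7 clusters on a 75.4 um perimeter -> 10.8 um gaps
    ang <- woundring:::with_seed(s, {
      (seq_len(n) - 0.5) * 2 * pi / n + stats::rnorm(n, sd = 1 / 12)
    })
    cfg <- quick_config(cluster_specs = cluster_spec(rep("radial", n), ang),
                        n_frames = 1L, seed = s)
    res <- run_cluster_pipeline(simulate_ring_movie(cfg))
    cluster_spacing(res$det, res$ds)
  }, numeric(1))
  expect_equal(mean(sp), 2 * pi * 12 / 7, tolerance = 0.15)
})

test_that("linking keeps two stalled clusters as two full-length tracks", {
  cfg <- quick_config(cluster_specs = cluster_spec(c("radial", "radial"),
                                                   c(0.8, pi)),
                      n_frames = 121L)
  res <- run_cluster_pipeline(simulate_ring_movie(cfg))
  summ <- attr(res$classified, "track_summary")
  expect_equal(nrow(summ), 2L)
  expect_equal(summ$lifetime_min, c(120, 120))
  expect_equal(nrow(attr(res$tracks, "fusions")), 0L)
})

test_that("converging clusters produce a single fusion event near merging", {
  # gap 6 um closed at 0.45 um/min; peaks blur together near ~1 um
  cfg <- sim_config(image_size_px = c(160L, 160L), ring_diameter0_um = 24,
                    closure_velocity_um_per_min = 0,
                    cluster_specs = cluster_spec(c("tangential", "tangential"),
                                                 c(0.5, 1.0),
                                                 speed_um_min = c(0.5, 0.05)),
                    junction_angles_rad = numeric(0),
                    cluster_jitter_speed_um_min = 0,
                    n_frames = 26L, gaussian_sd = 0, seed = 1)
  res <- run_cluster_pipeline(simulate_ring_movie(cfg))
  fus <- attr(res$tracks, "fusions")
  expect_equal(nrow(fus), 1L)
  expect_gte(fus$frame, 9L)
  expect_lte(fus$frame, 15L)
})

test_that("empty detections give empty tracks", {
  det <- detect_clusters(build_kymograph(
    array(100, dim = c(96, 96, 2)),
    tibble::tibble(frame = 1:2, time_min = 0:1, cx_um = 19.2, cy_um = 19.2,
                   radius_um = 12),
    pixel_size_um = 0.4, frame_interval_s = 60))
  tr <- link_tracks(det, tibble::tibble(frame = 1:2, radius_um = 12))
  expect_equal(nrow(tr), 0L)
  cl <- filter_and_classify(tr, tibble::tibble(frame = 1:2, radius_um = 12))
  expect_equal(nrow(cl), 0L)
})

test_that("lifetime filter drops short tracks and is idempotent", {
  geom <- tibble::tibble(frame = 1:20, radius_um = 12)
  mk <- function(id, frames) tibble::tibble(
    frame = frames, time_min = frames - 1, bin = 1,
    angle_rad = 0.01 * frames + id, arc_um = 12 * (0.01 * frames + id),
    intensity = 200, contrast = 1.5, track_id = id)
  det <- dplyr::bind_rows(mk(1L, 1:6), mk(2L, 1:20), mk(3L, 5:5))
  cl1 <- filter_and_classify(det, geom) # track 1: lifetime 5 -> dropped
  expect_equal(sort(unique(cl1$track_id)), 2L)
  cl2 <- filter_and_classify(cl1, geom)
  expect_equal(as.data.frame(cl1), as.data.frame(cl2))
})

test_that("class speeds are recovered and thresholded correctly", {
  cfg <- sim_config(cluster_specs = cluster_layout(2, 2),
                    n_frames = 41L, seed = 6)
  res <- run_cluster_pipeline(simulate_ring_movie(cfg))
  summ <- attr(res$classified, "track_summary")
  expect_equal(nrow(summ), 4L)
  expect_equal(sum(summ$class == "radial"), 2L)
  expect_equal(sum(summ$class == "tangential"), 2L)
  expect_lt(max(summ$speed_um_min[summ$class == "radial"]), 0.1)
  expect_gt(min(summ$speed_um_min[summ$class == "tangential"]), 0.1)
})

test_that("ring summary reports fractions, density and flags empty rings", {
  cfg <- quick_config(cluster_specs = cluster_layout(3, 1), n_frames = 15L,
                      cluster_jitter_speed_um_min = 0.05)
  res <- run_cluster_pipeline(simulate_ring_movie(cfg))
  expect_equal(res$summary$radial_fraction, 0.75)
  expect_equal(res$summary$cluster_density_per_um, 4 / (2 * pi * 12),
               tolerance = 0.1)
  # zero tracks -> undefined fraction, zero density
  blank <- run_cluster_pipeline(simulate_ring_movie(
    quick_config(n_frames = 8L)))
  expect_message(s <- summarize_ring(blank$classified, blank$ds),
                 "undefined")
  expect_true(is.na(s$radial_fraction))
  expect_equal(s$cluster_density_per_um, 0)
})

test_that("classification is invariant under frame mirroring", {
  cfg <- quick_config(cluster_specs = cluster_layout(1, 1), n_frames = 21L,
                      cluster_jitter_speed_um_min = 0.05,
                      gaussian_sd = 2, seed = 8)
  mov <- simulate_ring_movie(cfg)
  res <- run_cluster_pipeline(mov)
  mirrored <- mov
  mirrored$frames <- mov$frames[rev(seq_len(dim(mov$frames)[1])), , ,
                                drop = FALSE]
  res_m <- run_cluster_pipeline(mirrored)
  s1 <- attr(res$classified, "track_summary")
  s2 <- attr(res_m$classified, "track_summary")
  expect_equal(sort(s1$class), sort(s2$class))
  expect_equal(sort(s1$speed_um_min), sort(s2$speed_um_min), tolerance = 0.02)
})
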