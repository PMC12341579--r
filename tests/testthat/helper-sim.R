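# Shared fixtures: small, fast synthetic scenes for unit tests.
# Full-scale study conditions (50 um ring, 0.2 um/px) are exercised in
# test-acceptance.R; these helpers shrink the scene to keep unit tests quick.

quick_config <- function(...) {
  defaults <- list(
    image_size_px = c(96L, 96L),
    pixel_size_um = 0.4,
    ring_diameter0_um = 24,
    closure_velocity_um_per_min = 0,
    n_frames = 10L,
    gaussian_sd = 0,
    junction_angles_rad = numeric(0),
    cluster_jitter_speed_um_min = 0,
    cluster_specs = cluster_spec()
  )
  args <- list(...)
  defaults[names(args)] <- args
  do.call(sim_config, defaults)
}

# Run the detection -> linking -> classification pipeline on a movie.
run_cluster_pipeline <- function(mov, ...) {
  ds <- suppressMessages(diameter_series(mov))
  ky <- build_kymograph(mov, ds)
  det <- detect_clusters(ky, ...)
  tr <- link_tracks(det, ds)
  cl <- filter_and_classify(tr, ds)
  list(ds = ds, ky = ky, det = det, tracks = tr, classified = cl,
       summary = suppressMessages(summarize_ring(cl, ds)))
}

# Hand-built diameter series (for velocity / closure-time unit tests).
make_series <- function(times_min, diameters_um, pixel_size_um = 0.2) {
  out <- tibble::tibble(
    frame = seq_along(times_min),
    time_min = times_min,
    cx_um = 0, cy_um = 0,
    radius_um = diameters_um / 2,
    diameter_um = diameters_um,
    quality = 2,
    status = ifelse(diameters_um <= 0, "closed", "tracked")
  )
  structure(out, class = c("diameter_series", class(out)),
            t0_index = 1L, pixel_size_um = pixel_size_um,
            frame_interval_s = diff(times_min)[1] * 60)
}

# Brute-force two-sided Mann-Whitney p by enumerating every assignment of
# the pooled values to the two groups (no ties assumed).
enumerate_rank_sum_p <- function(a, b) {
  m <- length(a)
  pooled <- c(a, b)
  n_tot <- length(pooled)
  u_of <- function(idx) {
    x <- pooled[idx]
    y <- pooled[-idx]
    sum(outer(x, y, ">"))
  }
  u_obs <- u_of(seq_len(m))
  us <- apply(utils::combn(n_tot, m), 2, u_of)
  p_lo <- mean(us <= u_obs)
  p_hi <- mean(us >= u_obs)
  min(1, 2 * min(p_lo, p_hi))
}
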