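#' Configuration for the synthetic wound-ring movie generator
#'
#' Bundles the imaging calibration and scene parameters used by
#' [simulate_ring_movie()] and [simulate_fret_sequence()]. Defaults emulate
#' the study conditions the package targets: a 50 um diameter actomyosin
#' ring imaged at 0.2 um/px and 1 min/frame, closing at 0.125 um/min of
#' diameter (full closure in ~400 min), with a Gaussian cable tube enriched
#' 1.9x over the epithelium base and micrometre-scale myosin clusters.
#'
#' @param image_size_px integer length-2, frame size in pixels (rows, cols).
#' @param pixel_size_um pixel size in um/px.
#' @param frame_interval_s time between frames in seconds.
#' @param n_frames number of frames.
#' @param ring_diameter0_um initial ring diameter (um).
#' @param closure_velocity_um_per_min rate of diameter decrease (um/min,
#'   >= 0; 0 stalls the ring, as when a pillar is left in the wound).
#' @param cable_width_um Gaussian sigma of the cable tube cross-section (um).
#' @param cable_enrichment cable centreline intensity relative to the
#'   epithelium base (>= 1).
#' @param base_intensity epithelium base intensity (a.u.).
#' @param cluster_specs tibble describing clusters, as returned by
#'   [cluster_spec()]; may have zero rows.
#' @param junction_angles_rad angular positions of cell-cell junctions on
#'   the ring; clusters reflect at junctions and cannot cross them.
#' @param cluster_jitter_speed_um_min residual arc speed (mean |arc step| per
#'   minute) of the stochastic positional jitter applied to every cluster;
#'   this is what makes "still" radial clusters move at a small but nonzero
#'   measured speed. Set 0 for exact deterministic trajectories.
#' @param cluster_jitter_corr_min correlation time (min) of the
#'   Ornstein-Uhlenbeck jitter.
#' @param gaussian_sd additive Gaussian read-noise sd (a.u.).
#' @param poisson_noise if `TRUE`, draw each pixel from a Poisson law with
#'   the noiseless intensity as mean before adding read noise.
#' @param seed integer seed; equal seeds give bit-identical output.
#'
#' @return An object of class `sim_config` (a named list, validated).
#' @export
sim_config <- function(image_size_px = c(288L, 288L),
                       pixel_size_um = 0.2,
                       frame_interval_s = 60,
                       n_frames = 61L,
                       ring_diameter0_um = 50,
                       closure_velocity_um_per_min = 0.125,
                       cable_width_um = 0.25,
                       cable_enrichment = 1.9,
                       base_intensity = 100,
                       cluster_specs = cluster_spec(),
                       junction_angles_rad = seq(0, 2 * pi, length.out = 7L)[-7L] + pi / 6,
                       cluster_jitter_speed_um_min = 0.05,
                       cluster_jitter_corr_min = 10,
                       gaussian_sd = 3,
                       poisson_noise = FALSE,
                       seed = 1L) {
  stopifnot_scalar_pos(pixel_size_um, "pixel_size_um")
  stopifnot_scalar_pos(frame_interval_s, "frame_interval_s")
  stopifnot_scalar_pos(ring_diameter0_um, "ring_diameter0_um")
  if (length(image_size_px) != 2L || any(image_size_px < 32)) {
    abort("`image_size_px` must be two integers >= 32.")
  }
  if (closure_velocity_um_per_min < 0) {
    abort("`closure_velocity_um_per_min` must be >= 0.")
  }
  if (cable_enrichment < 1) abort("`cable_enrichment` must be >= 1.")
  if (gaussian_sd < 0) abort("`gaussian_sd` (noise sd) must be >= 0.")
  if (cluster_jitter_speed_um_min < 0) {
    abort("`cluster_jitter_speed_um_min` must be >= 0.")
  }
  cluster_specs <- as_tibble(cluster_specs)
  needed <- c("class", "angle0_rad", "speed_um_min", "amplitude", "sigma_um")
  if (!all(needed %in% names(cluster_specs))) {
    abort(paste("`cluster_specs` must have columns:",
                paste(needed, collapse = ", ")))
  }
  if (nrow(cluster_specs) > 0) {
    if (!all(cluster_specs$class %in% c("radial", "tangential"))) {
      abort("cluster class must be 'radial' or 'tangential'.")
    }
    if (any(cluster_specs$sigma_um <= 0)) abort("cluster sigma_um must be > 0.")
  }
  junction_angles_rad <- wrap_angle(junction_angles_rad)
  if (anyDuplicated(round(junction_angles_rad, 9))) {
    abort("junction angles overlap.")
  }
  # The full ring plus cable tube must fit in the field of view.
  fov_um <- min(image_size_px) * pixel_size_um
  if (ring_diameter0_um + 8 * cable_width_um >= fov_um) {
    abort("ring larger than the field of view.")
  }
  structure(list(
    image_size_px = as.integer(image_size_px),
    pixel_size_um = pixel_size_um,
    frame_interval_s = frame_interval_s,
    n_frames = as.integer(n_frames),
    ring_diameter0_um = ring_diameter0_um,
    closure_velocity_um_per_min = closure_velocity_um_per_min,
    cable_width_um = cable_width_um,
    cable_enrichment = cable_enrichment,
    base_intensity = base_intensity,
    cluster_specs = cluster_specs,
    junction_angles_rad = sort(junction_angles_rad),
    cluster_jitter_speed_um_min = cluster_jitter_speed_um_min,
    cluster_jitter_corr_min = cluster_jitter_corr_min,
    gaussian_sd = gaussian_sd,
    poisson_noise = poisson_noise,
    seed = seed
  ), class = "sim_config")
}

#' Describe synthetic myosin clusters
#'
#' Builds the `cluster_specs` table consumed by [sim_config()]. With no
#' arguments returns an empty (zero-cluster) specification.
#'
#' @param class character vector, `"radial"` or `"tangential"` per cluster.
#' @param angle0_rad initial angular position of each cluster (rad).
#' @param speed_um_min deterministic tangential arc speed (um/min); radial
#'   clusters use 0 (their residual motion comes from the configured jitter),
#'   tangential clusters typically 0.2.
#' @param amplitude peak intensity added by the cluster (a.u.).
#' @param sigma_um isotropic Gaussian sigma of the rendered cluster (um);
#'   0.4 um gives a FWHM close to the ~1 um apparent cluster size.
#' @return A tibble with one row per cluster.
#' @export
cluster_spec <- function(class = character(),
                         angle0_rad = numeric(),
                         speed_um_min = ifelse(class == "radial", 0, 0.2),
                         amplitude = rep(250, length(class)),
                         sigma_um = rep(0.4, length(class))) {
  tibble(
    class = as.character(class),
    angle0_rad = wrap_angle(as.numeric(angle0_rad)),
    speed_um_min = as.numeric(speed_um_min),
    amplitude = as.numeric(amplitude),
    sigma_um = as.numeric(sigma_um)
  )
}

#' Evenly spaced mixed cluster layout
#'
#' Convenience layout placing `n_radial` + `n_tangential` clusters at evenly
#' spaced angles (offset to sit between the default junction positions).
#'
#' @param n_radial,n_tangential counts per class.
#' @inheritParams cluster_spec
#' @return A tibble as from [cluster_spec()].
#' @export
cluster_layout <- function(n_radial = 2L, n_tangential = 2L,
                           speed_um_min = 0.2, amplitude = 250,
                           sigma_um = 0.4) {
  n <- n_radial + n_tangential
  if (n == 0L) return(cluster_spec())
  classes <- c(rep("radial", n_radial), rep("tangential", n_tangential))
  # small offset so no cluster starts exactly on a default junction
  angles <- seq(0, 2 * pi, length.out = n + 1L)[seq_len(n)] + pi / 12

  cluster_spec(
    class = classes,
    angle0_rad = angles,
    speed_um_min = ifelse(classes == "radial", 0, speed_um_min),
    amplitude = rep(amplitude, n),
    sigma_um = rep(sigma_um, n)
  )
}
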