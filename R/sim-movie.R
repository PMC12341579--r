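#' Simulate a constricting wound-ring movie with ground truth
#'
#' Renders a time-lapse of an epithelial wound ring: a uniform epithelium
#' base carrying a bright circular actomyosin cable (Gaussian tube
#' cross-section) whose radius shrinks linearly,
#' `R(t) = R0 - (closure_velocity / 2) * t` (clamped at 0), plus Gaussian
#' myosin clusters riding on the cable. Radial clusters keep a constant
#' angular position up to Ornstein-Uhlenbeck jitter; tangential clusters
#' advance along the perimeter at their configured arc speed. Clusters
#' reflect elastically at cell-cell junction angles and never cross them.
#'
#' @param config a [sim_config()] object.
#' @return A list of class `ring_movie` with elements
#'   \describe{
#'     \item{frames}{numeric array `[rows, cols, n_frames]` (a.u.).}
#'     \item{config}{the input configuration.}
#'     \item{truth}{list with `geometry` (tibble: frame, time_min, cx_um,
#'       cy_um, radius_um), `clusters` (tibble: cluster, frame, time_min,
#'       class, angle_rad, arc_um), and `closure_time_min` (`NA` if the ring
#'       never closes within the movie).}
#'   }
#' @examples
#' cfg <- sim_config(n_frames = 3L, gaussian_sd = 0)
#' mov <- simulate_ring_movie(cfg)
#' dim(mov$frames)
#' @export
simulate_ring_movie <- function(config) {
  if (!inherits(config, "sim_config")) abort("`config` must be a sim_config.")
  with_seed(config$seed, {
    dt_min <- config$frame_interval_s / 60
    nT <- config$n_frames
    times_min <- (seq_len(nT) - 1) * dt_min
    R0 <- config$ring_diameter0_um / 2
    radii <- pmax(R0 - (config$closure_velocity_um_per_min / 2) * times_min, 0)
    center <- c(config$image_size_px[2], config$image_size_px[1]) *
      config$pixel_size_um / 2

    angles <- simulate_cluster_angles(config, radii, dt_min)

    frames <- array(0, dim = c(config$image_size_px[1], config$image_size_px[2], nT))
    nr <- config$image_size_px[1]
    nc <- config$image_size_px[2]
    xs <- ((seq_len(nc)) - 0.5) * config$pixel_size_um
    ys <- ((seq_len(nr)) - 0.5) * config$pixel_size_um
    xmat <- matrix(xs, nr, nc, byrow = TRUE)
    ymat <- matrix(ys, nr, nc)
    rmat <- sqrt((xmat - center[1])^2 + (ymat - center[2])^2)

    nclu <- nrow(config$cluster_specs)
    for (t in seq_len(nT)) {
      f <- config$base_intensity *
        (1 + (config$cable_enrichment - 1) *
           exp(-(rmat - radii[t])^2 / (2 * config$cable_width_um^2)))
      if (nclu > 0) {
        for (k in seq_len(nclu)) {
          f <- add_gaussian_blob(
            f,
            x0 = center[1] + radii[t] * cos(angles[t, k]),
            y0 = center[2] + radii[t] * sin(angles[t, k]),
            amplitude = config$cluster_specs$amplitude[k],
            sigma_um = config$cluster_specs$sigma_um[k],
            pixel_size_um = config$pixel_size_um
          )
        }
      }
      if (config$poisson_noise) {
        f[] <- stats::rpois(length(f), lambda = pmax(f, 0))
      }
      if (config$gaussian_sd > 0) {
        f <- f + stats::rnorm(length(f), sd = config$gaussian_sd)
      }
      frames[, , t] <- f
    }

    geometry <- tibble(
      frame = seq_len(nT),
      time_min = times_min,
      cx_um = center[1],
      cy_um = center[2],
      radius_um = radii
    )
    clusters <- if (nclu > 0) {
      tidyr::expand_grid(cluster = seq_len(nclu), frame = seq_len(nT)) |>
        dplyr::mutate(
          time_min = times_min[.data$frame],
          class = config$cluster_specs$class[.data$cluster],
          angle_rad = wrap_angle(angles[cbind(.data$frame, .data$cluster)]),
          arc_um = radii[.data$frame] * .data$angle_rad
        ) |>
        dplyr::arrange(.data$cluster, .data$frame)
    } else {
      tibble(cluster = integer(), frame = integer(), time_min = numeric(),
             class = character(), angle_rad = numeric(), arc_um = numeric())
    }
    closure_time_min <- if (config$closure_velocity_um_per_min > 0) {
      ct <- config$ring_diameter0_um / config$closure_velocity_um_per_min
      if (ct <= max(times_min)) ct else NA_real_
    } else NA_real_

    structure(list(
      frames = frames,
      config = config,
      truth = list(geometry = geometry, clusters = clusters,
                   closure_time_min = closure_time_min)
    ), class = "ring_movie")
  })
}

# Add an isotropic Gaussian blob, evaluated only on a +/- 4 sigma window.
add_gaussian_blob <- function(img, x0, y0, amplitude, sigma_um, pixel_size_um) {
  nr <- nrow(img)
  nc <- ncol(img)
  half_px <- ceiling(4 * sigma_um / pixel_size_um)
  j0 <- round(x0 / pixel_size_um + 0.5)
  i0 <- round(y0 / pixel_size_um + 0.5)
  jj <- max(1L, j0 - half_px):min(nc, j0 + half_px)
  ii <- max(1L, i0 - half_px):min(nr, i0 + half_px)
  if (length(jj) == 0L || length(ii) == 0L) return(img)
  xs <- (jj - 0.5) * pixel_size_um
  ys <- (ii - 0.5) * pixel_size_um
  d2 <- outer((ys - y0)^2, (xs - x0)^2, "+")
  img[ii, jj] <- img[ii, jj] + amplitude * exp(-d2 / (2 * sigma_um^2))
  img
}

# Per-frame cluster angles (matrix n_frames x n_clusters), unwrapped only
# locally: values are kept continuous within a trajectory so reflections
# can be applied, but returned wrapped by the caller.
#
# Jitter: an Ornstein-Uhlenbeck arc offset whose stationary increments have
# mean absolute step `jitter_speed * dt`, converted to angle at the current
# radius. Tangential drift advances theta by speed * dt / R(t) so the arc
# speed |R dtheta/dt| matches the configured value.
simulate_cluster_angles <- function(config, radii, dt_min) {
  nT <- length(radii)
  specs <- config$cluster_specs
  nclu <- nrow(specs)
  ang <- matrix(NA_real_, nT, max(nclu, 1L))
  if (nclu == 0L) return(ang)

  phi <- if (config$cluster_jitter_corr_min > 0) {
    exp(-dt_min / config$cluster_jitter_corr_min)
  } else 0
  # innovation sd so stationary |increment| of the arc offset averages
  # jitter_speed * dt  (E|N(0,s)| = s * sqrt(2/pi), var(du) = 2 s_eta^2/(1+phi))
  sd_eta <- config$cluster_jitter_speed_um_min * dt_min *
    sqrt(pi / 2) * sqrt((1 + phi) / 2)
  junctions <- config$junction_angles_rad

  for (k in seq_len(nclu)) {
    theta <- numeric(nT)
    theta[1] <- specs$angle0_rad[k]
    dir <- 1
    u_prev <- if (sd_eta > 0) stats::rnorm(1, sd = sd_eta / sqrt(1 - phi^2)) else 0
    for (t in seq_len(nT - 1L)) {
      R <- max(radii[t], 1e-6)
      u_new <- phi * u_prev + if (sd_eta > 0) stats::rnorm(1, sd = sd_eta) else 0
      drift <- if (specs$class[k] == "tangential") {
        dir * specs$speed_um_min[k] * dt_min / R
      } else 0
      step <- drift + (u_new - u_prev) / R
      prop <- theta[t] + step
      refl <- reflect_at_junctions(theta[t], prop, junctions)
      if (refl$reflected) dir <- -dir
      theta[t + 1L] <- refl$theta
      u_prev <- u_new
    }
    ang[, k] <- theta
  }
  ang
}

# Elastic reflection of a small angular step at the nearest crossed
# junction. Steps are small (<< segment length), so at most one junction
# can be crossed per step.
reflect_at_junctions <- function(old, prop, junctions) {
  if (length(junctions) == 0L) return(list(theta = prop, reflected = FALSE))
  step <- prop - old
  if (step == 0) return(list(theta = prop, reflected = FALSE))
  # signed angular distance from old to each junction, in step direction
  d <- angle_diff(junctions, old)
  crossed <- if (step > 0) which(d > 0 & d < step) else which(d < 0 & d > step)
  if (length(crossed) == 0L) return(list(theta = prop, reflected = FALSE))
  dj <- d[crossed][which.min(abs(d[crossed]))]
  theta_j <- old + dj
  list(theta = 2 * theta_j - prop, reflected = TRUE)
}
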