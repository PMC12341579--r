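#' Unwrap the ring into a circumferential intensity profile
#'
#' Samples the frame on a polar band around the fitted ring: for each of
#' `n_angle_bins` angular bins the profile value is the mean of bilinear
#' samples over radii `R - h .. R + h` at that bin's angle (angle measured
#' counter-clockwise from +x). A companion "ridge" profile holds the cable
#' centreline intensity -- the parabolic-refined radial peak at that angle
#' -- used for cable concentration and contrast statistics.
#'
#' @param frame numeric matrix (a.u.).
#' @param geometry one-row tibble/list with `cx_um`, `cy_um`, `radius_um`.
#' @param pixel_size_um pixel size (um/px).
#' @param band_halfwidth_um half-width `h` of the radial band (um).
#' @param n_angle_bins number of angular bins; defaults to one bin per
#'   pixel of arc, `round(2 * pi * R / pixel_size_um)`.
#' @return A tibble with `bin`, `angle_rad`, `arc_um`, `intensity` (band
#'   mean) and `ridge_intensity` (centreline sample).
#' @export
unwrap_ring <- function(frame, geometry, pixel_size_um,
                        band_halfwidth_um = 1, n_angle_bins = NULL) {
  prof <- unwrap_profiles(frame, geometry, pixel_size_um,
                          band_halfwidth_um, n_angle_bins)
  tibble(
    bin = seq_along(prof$band),
    angle_rad = prof$theta,
    arc_um = geometry$radius_um * prof$theta,
    intensity = prof$band,
    ridge_intensity = prof$ridge
  )
}

# Fast internal polar unwrap; returns list(theta, band, ridge).
unwrap_profiles <- function(frame, geometry, pixel_size_um,
                            band_halfwidth_um, n_angle_bins = NULL) {
  stopifnot_scalar_pos(pixel_size_um, "pixel_size_um")
  R <- geometry$radius_um
  if (!is.finite(R) || R <= 0) abort("geometry has no positive radius.")
  n <- n_angle_bins %||% max(16L, round(2 * pi * R / pixel_size_um))
  theta <- (seq_len(n) - 0.5) * 2 * pi / n
  # midpoint rule: samples represent pixel_size-wide cells tiling [-h, h]
  h <- band_halfwidth_um
  offs <- if (h >= pixel_size_um) {
    seq(-h + pixel_size_um / 2, h - pixel_size_um / 2, by = pixel_size_um)
  } else 0
  radii <- R + offs
  radii <- radii[radii > 0]
  if (length(radii) == 0L) radii <- max(R, pixel_size_um / 2)
  # sample matrix: rows = radii, cols = bins
  ct <- cos(theta)
  st <- sin(theta)
  xg <- geometry$cx_um + outer(radii, ct)
  yg <- geometry$cy_um + outer(radii, st)
  w_um <- ncol(frame) * pixel_size_um
  h_um <- nrow(frame) * pixel_size_um
  if (any(xg < 0 | xg > w_um | yg < 0 | yg > h_um)) {
    warn("sampling band exits the image; border samples clipped.")
  }
  vals <- matrix(bilinear_sample(frame, as.numeric(xg), as.numeric(yg),
                                 pixel_size_um),
                 nrow = length(radii))
  band <- colMeans(vals)
  # centreline intensity: radial peak per angle, parabolic-refined so the
  # cable's Gaussian cross-section is not attenuated by grid interpolation
  at_R <- bilinear_sample(frame, geometry$cx_um + R * ct,
                          geometry$cy_um + R * st, pixel_size_um)
  ridge <- if (length(radii) < 3L) at_R else {
    vapply(seq_len(n), function(j) {
      v <- vals[, j]
      i <- which.max(v)
      if (i == 1L || i == length(v)) return(at_R[j])
      denom <- v[i - 1L] - 2 * v[i] + v[i + 1L]
      if (!is.finite(denom) || denom >= -1e-12) return(v[i])
      v[i] - (v[i - 1L] - v[i + 1L])^2 / (8 * denom)
    }, numeric(1))
  }
  list(theta = theta, band = band, ridge = ridge)
}

#' Assemble the circumferential kymograph of a movie
#'
#' Unwraps every tracked frame with a common, fixed number of angular bins
#' so that a cluster keeping constant angular position appears as a
#' vertical ridge in the angle-time plane even while the ring constricts
#' (arc positions are reported as `s = R(t) * theta`). Frames without valid
#' geometry (closed or lost) become `NA` columns.
#'
#' @param movie a `ring_movie` or numeric array `[rows, cols, frames]`.
#' @param geometry_series a [diameter_series()] tibble (or any tibble with
#'   `frame`, `time_min`, `cx_um`, `cy_um`, `radius_um`).
#' @param band_halfwidth_um radial half-width of the sampling band (um).
#' @param n_angle_bins fixed angular bin count; defaults to one bin per
#'   pixel of arc at the first tracked frame.
#' @param pixel_size_um,frame_interval_s calibration; read from the movie
#'   object when available.
#' @return An object of class `kymograph`: list with `values` and `ridge`
#'   (matrices, angle bins x frames), `angle_rad`, `geometry`,
#'   `base_intensity` (per-frame background estimate from an annulus
#'   outside the band), `band_halfwidth_um`, `pixel_size_um`,
#'   `frame_interval_s`.
#' @export
build_kymograph <- function(movie, geometry_series,
                            band_halfwidth_um = 1, n_angle_bins = NULL,
                            pixel_size_um = NULL, frame_interval_s = NULL) {
  if (inherits(movie, "ring_movie")) {
    frames <- movie$frames
    pixel_size_um <- pixel_size_um %||% movie$config$pixel_size_um
    frame_interval_s <- frame_interval_s %||% movie$config$frame_interval_s
  } else {
    frames <- movie
    pixel_size_um <- pixel_size_um %||% attr(geometry_series, "pixel_size_um")
    frame_interval_s <- frame_interval_s %||% attr(geometry_series, "frame_interval_s")
  }
  if (is.null(pixel_size_um) || is.null(frame_interval_s)) {
    abort("calibration not found; supply `pixel_size_um` and `frame_interval_s`.")
  }
  nT <- dim(frames)[3]
  geom <- as_tibble(geometry_series)
  ok <- is.finite(geom$radius_um) & geom$radius_um > 0
  if (!any(ok)) abort("geometry series has no tracked frame.")
  first <- geom$frame[which(ok)[1]]
  R1 <- geom$radius_um[which(ok)[1]]
  n <- n_angle_bins %||% max(16L, round(2 * pi * R1 / pixel_size_um))
  theta <- (seq_len(n) - 0.5) * 2 * pi / n

  values <- matrix(NA_real_, n, nT)
  ridge <- matrix(NA_real_, n, nT)
  base <- rep(NA_real_, nT)
  peak <- rep(NA_real_, nT)
  for (t in seq_len(nT)) {
    g <- geom[geom$frame == t, ]
    if (nrow(g) != 1L || !is.finite(g$radius_um) || g$radius_um <= 0) next
    prof <- unwrap_profiles(frames[, , t], g, pixel_size_um,
                            band_halfwidth_um, n_angle_bins = n)
    values[, t] <- prof$band
    ridge[, t] <- prof$ridge
    base[t] <- estimate_base(frames[, , t], g, pixel_size_um,
                             r_offset_um = 2.5 * band_halfwidth_um)
    peak[t] <- cable_peak_intensity(frames[, , t], g, pixel_size_um, base[t])
  }
  structure(list(
    values = values, ridge = ridge, angle_rad = theta,
    geometry = geom, base_intensity = base, peak_intensity = peak,
    band_halfwidth_um = band_halfwidth_um,
    n_angle_bins = n,
    pixel_size_um = pixel_size_um,
    frame_interval_s = frame_interval_s
  ), class = "kymograph")
}

# Cable centreline peak intensity from raw pixel values: pixels within
# 1.5 um of the fitted radius are binned by their exact radial distance
# and the angle-averaged profile's peak is refined log-parabolically,
# which is exact for the Gaussian tube cross-section. Avoids the
# interpolation attenuation a bilinear read-out at r = R would suffer.
cable_peak_intensity <- function(frame, geometry, pixel_size_um, base) {
  R <- geometry$radius_um
  if (!is.finite(R) || R < 2) return(NA_real_)
  nr <- nrow(frame)
  nc <- ncol(frame)
  xs <- (seq_len(nc) - 0.5) * pixel_size_um - geometry$cx_um
  ys <- (seq_len(nr) - 0.5) * pixel_size_um - geometry$cy_um
  rmat <- sqrt(outer(ys^2, xs^2, "+"))
  sel <- abs(rmat - R) <= 1.5
  if (!any(sel)) return(NA_real_)
  r <- rmat[sel]
  v <- frame[sel]
  bw <- pixel_size_um / 2
  bin <- round((r - R) / bw)
  prof <- tapply(v, bin, mean)
  centers <- as.numeric(names(prof)) * bw
  i <- which.max(prof)
  lo <- max(1L, i - 3L)
  hi <- min(length(prof), i + 3L)
  y <- prof[lo:hi] - (if (is.finite(base)) base else min(prof))
  x <- centers[lo:hi]
  if (length(y) < 3L || any(y <= 0)) return(max(prof))
  co <- stats::coef(stats::lm(log(y) ~ x + I(x^2)))
  if (!is.finite(co[3]) || co[3] >= 0) return(max(prof))
  peak_log <- co[1] - co[2]^2 / (4 * co[3])
  exp(peak_log) + (if (is.finite(base)) base else min(prof))
}

# Background (epithelium base) estimate: mean intensity on a circle well
# outside the cable band, clipped to stay inside the image.
estimate_base <- function(frame, geometry, pixel_size_um, r_offset_um) {
  r <- geometry$radius_um + r_offset_um
  rmax <- min(geometry$cx_um, geometry$cy_um,
              ncol(frame) * pixel_size_um - geometry$cx_um,
              nrow(frame) * pixel_size_um - geometry$cy_um) - pixel_size_um
  r <- min(r, rmax)
  if (r <= 0) return(stats::median(frame))
  mean(radial_profile(frame, c(geometry$cx_um, geometry$cy_um), r,
                      pixel_size_um, n_angles = 180L))
}

#' Per-frame cable statistics from a kymograph
#'
#' Measures, per tracked frame, the cable mean (centreline) intensity, the
#' band-integrated total intensity, the ring perimeter and the cable
#' contrast over the epithelium base (the angle-averaged radial-profile
#' peak, from a Gaussian-consistent fit on raw pixels, divided by the
#' annulus background). During constriction at constant
#' actomyosin concentration the mean stays flat while the total decreases
#' in proportion to the perimeter.
#'
#' @param kymograph a [build_kymograph()] object.
#' @param base_intensity scalar background estimate (a.u.); defaults to
#'   the per-frame annulus estimate stored in the kymograph.
#' @return A tibble with `frame`, `time_min`, `perimeter_um`,
#'   `mean_intensity`, `total_intensity`, `contrast_vs_base`.
#' @export
cable_stats <- function(kymograph, base_intensity = NULL) {
  if (!inherits(kymograph, "kymograph")) abort("`kymograph` required.")
  geom <- kymograph$geometry
  dt_min <- kymograph$frame_interval_s / 60
  nT <- ncol(kymograph$values)
  base <- base_intensity %||% kymograph$base_intensity
  if (length(base) == 1L) base <- rep(base, nT)
  if (any(is.finite(base) & base <= 0)) abort("base intensity must be > 0.")
  purrr::map_dfr(seq_len(nT), function(t) {
    col <- kymograph$values[, t]
    if (all(is.na(col))) {
      return(tibble(frame = t, time_min = (t - 1) * dt_min,
                    perimeter_um = NA_real_, mean_intensity = NA_real_,
                    total_intensity = NA_real_, contrast_vs_base = NA_real_))
    }
    R <- geom$radius_um[match(t, geom$frame)]
    per <- 2 * pi * R
    m <- mean(kymograph$ridge[, t], na.rm = TRUE)
    tot <- mean(col, na.rm = TRUE) * per
    pk <- kymograph$peak_intensity[t]
    if (!is.finite(pk)) pk <- m
    tibble(frame = t, time_min = (t - 1) * dt_min,
           perimeter_um = per, mean_intensity = m,
           total_intensity = tot, contrast_vs_base = pk / base[t])
  })
}
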