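#' Detect the wound ring in a single frame
#'
#' Locates the bright circular actomyosin cable: the centre is the
#' intensity-weighted centroid of the cable mask (Otsu threshold, falling
#' back to mean + 2 sd), and the radius is the peak of the radial
#' mean-intensity profile about that centre, refined to sub-pixel precision
#' by 3-point parabolic interpolation. With a `prior` geometry the radius
#' search is restricted to +/- 20% of the prior radius.
#'
#' @param frame numeric matrix (a.u.), at least 32 x 32 px.
#' @param pixel_size_um pixel size (um/px).
#' @param prior optional one-row tibble (or list) with `cx_um`, `cy_um`,
#'   `radius_um` from a previous frame.
#' @param min_quality minimum cable contrast (profile peak / frame median)
#'   below which no ring is reported.
#' @param closed_radius_px radius (px) below which the ring is considered
#'   closed.
#' @return One-row tibble: `cx_um`, `cy_um`, `radius_um`, `diameter_um`,
#'   `quality`.
#' @section Errors: signals a classed error `woundring_ring_not_found` when
#'   no circular structure exceeds `min_quality`, and
#'   `woundring_ring_closed` when the fitted radius falls below
#'   `closed_radius_px`.
#' @export
detect_ring <- function(frame, pixel_size_um, prior = NULL,
                        min_quality = 1.2, closed_radius_px = 2) {
  if (!is.matrix(frame) || nrow(frame) < 32L || ncol(frame) < 32L) {
    abort("`frame` must be a numeric matrix of at least 32 x 32 px.")
  }
  stopifnot_scalar_pos(pixel_size_um, "pixel_size_um")
  ps <- pixel_size_um
  rng <- range(frame)
  if (diff(rng) < .Machine$double.eps * max(abs(rng), 1)) {
    abort("ring not found", class = "woundring_ring_not_found")
  }
  thr <- cable_threshold(frame)
  w <- pmax(frame - thr, 0)
  if (sum(w) <= 0) abort("ring not found", class = "woundring_ring_not_found")
  xs <- (seq_len(ncol(frame)) - 0.5) * ps
  ys <- (seq_len(nrow(frame)) - 0.5) * ps
  cx <- sum(w %*% xs) / sum(w)
  cy <- sum(ys %*% w) / sum(w)
  if (!is.null(prior)) {
    if (prior$cx_um < 0 || prior$cx_um > ncol(frame) * ps ||
        prior$cy_um < 0 || prior$cy_um > nrow(frame) * ps) {
      abort("prior centre lies outside the frame.")
    }
  }

  closed_um <- closed_radius_px * ps
  if (!is.null(prior)) {
    if (prior$radius_um * 1.2 < closed_um) {
      abort("ring closed", class = "woundring_ring_closed")
    }
    r_lo <- max(0.5 * ps, 0.8 * prior$radius_um)
    r_hi <- 1.2 * prior$radius_um
    step <- 0.25 * ps
  } else {
    r_lo <- ps
    r_hi <- min(cx, cy, ncol(frame) * ps - cx, nrow(frame) * ps - cy) - 2 * ps
    step <- 0.5 * ps
    if (r_hi <= r_lo) abort("ring not found", class = "woundring_ring_not_found")
  }
  radii <- seq(r_lo, r_hi, by = step)
  if (length(radii) < 3L) radii <- seq(r_lo, r_hi, length.out = 5L)
  prof <- radial_profile(frame, c(cx, cy), radii, ps)
  i <- which.max(prof)
  off <- if (i > 1L && i < length(prof)) {
    parabolic_offset(prof[i - 1L], prof[i], prof[i + 1L])
  } else 0
  r_hat <- radii[i] + off * diff(radii[1:2])
  # refine the centre against cluster-induced centroid bias: the per-angle
  # peak radius r(theta) ~ R + dx cos(theta) + dy sin(theta) for a small
  # centre offset (dx, dy)
  if (r_hat > 5 * ps) {
    for (iter in 1:2) {
      ref <- refine_circle(frame, c(cx, cy), r_hat, ps)
      if (is.null(ref)) break
      cx <- ref$cx
      cy <- ref$cy
      r_hat <- ref$R
    }
  }
  base <- stats::median(frame)
  quality <- if (base > 0) prof[i] / base else Inf
  if (quality < min_quality) {
    abort("ring not found", class = "woundring_ring_not_found")
  }
  if (r_hat < closed_um) abort("ring closed", class = "woundring_ring_closed")
  tibble(cx_um = cx, cy_um = cy, radius_um = r_hat,
         diameter_um = 2 * r_hat, quality = quality)
}

# One circle-refinement pass: locate the radial intensity peak per angle
# (parabolic sub-grid), then regress r(theta) on (1, cos, sin) to update
# centre and radius. Returns NULL when too few angles have a usable peak.
refine_circle <- function(frame, center, R0, ps, n_angles = 180L,
                          window_um = 2) {
  theta <- (seq_len(n_angles) - 0.5) * 2 * pi / n_angles
  radii <- seq(max(R0 - window_um, ps), R0 + window_um, by = ps / 2)
  if (length(radii) < 5L) return(NULL)
  xg <- center[1] + outer(radii, cos(theta))
  yg <- center[2] + outer(radii, sin(theta))
  vals <- matrix(bilinear_sample(frame, as.numeric(xg), as.numeric(yg), ps),
                 nrow = length(radii))
  step <- diff(radii[1:2])
  r_pk <- vapply(seq_len(n_angles), function(j) {
    v <- vals[, j]
    i <- which.max(v)
    if (i == 1L || i == length(v)) return(NA_real_)
    radii[i] + parabolic_offset(v[i - 1L], v[i], v[i + 1L]) * step
  }, numeric(1))
  ok <- is.finite(r_pk)
  if (sum(ok) < n_angles / 2) return(NULL)
  co <- stats::coef(stats::lm(r_pk[ok] ~ cos(theta[ok]) + sin(theta[ok])))
  if (!all(is.finite(co))) return(NULL)
  list(cx = center[1] + co[[2]], cy = center[2] + co[[3]], R = co[[1]])
}

# Otsu threshold on the frame (via EBImage), falling back to mean + 2 sd
# when the histogram is degenerate.
cable_threshold <- function(frame) {
  rng <- range(frame)
  thr <- tryCatch({
    scaled <- (frame - rng[1]) / diff(rng)
    EBImage::otsu(scaled, range = c(0, 1), levels = 256L) * diff(rng) + rng[1]
  }, error = function(e) NA_real_)
  if (!is.finite(thr)) thr <- mean(frame) + 2 * stats::sd(frame)
  thr
}

#' Track the ring diameter through a movie
#'
#' Runs [detect_ring()] frame by frame, each frame using the previous
#' geometry as prior. Once the ring is measured closed, the remaining
#' frames carry diameter 0. If tracking is lost mid-movie the series is
#' truncated with a warning. The analysis time origin `t0` follows the
#' onset convention: the first frame whose diameter lies within
#' `onset_um +/- onset_tol_um` (50 +/- 2 um by default).
#'
#' @param movie a `ring_movie` from [simulate_ring_movie()], or a numeric
#'   array `[rows, cols, frames]` (then `pixel_size_um` and
#'   `frame_interval_s` are required).
#' @param pixel_size_um,frame_interval_s calibration, read from the movie
#'   object when available.
#' @param t0_convention `"onset"` (first diameter within the onset window)
#'   or `"first"` (first frame).
#' @param onset_um,onset_tol_um the onset window (um).
#' @param ... passed to [detect_ring()].
#' @return A tibble of class `diameter_series` with columns `frame`,
#'   `time_min`, `cx_um`, `cy_um`, `radius_um`, `diameter_um`, `quality`,
#'   `status` (`"tracked"` or `"closed"`); attributes `t0_index`,
#'   `pixel_size_um`, `frame_interval_s`.
#' @export
diameter_series <- function(movie, pixel_size_um = NULL,
                            frame_interval_s = NULL,
                            t0_convention = c("onset", "first"),
                            onset_um = 50, onset_tol_um = 2, ...) {
  t0_convention <- match.arg(t0_convention)
  if (inherits(movie, "ring_movie")) {
    frames <- movie$frames
    pixel_size_um <- pixel_size_um %||% movie$config$pixel_size_um
    frame_interval_s <- frame_interval_s %||% movie$config$frame_interval_s
  } else {
    frames <- movie
  }
  if (is.null(pixel_size_um) || is.null(frame_interval_s)) {
    abort("supply `pixel_size_um` and `frame_interval_s` for a raw array.")
  }
  nT <- dim(frames)[3]
  dt_min <- frame_interval_s / 60
  rows <- vector("list", nT)
  prior <- NULL
  closed_from <- NA_integer_
  for (t in seq_len(nT)) {
    res <- tryCatch(
      detect_ring(frames[, , t], pixel_size_um, prior = prior, ...),
      woundring_ring_closed = function(e) "closed",
      woundring_ring_not_found = function(e) if (t == 1L) {
        abort("first-frame ring detection failed.",
              class = "woundring_ring_not_found")
      } else "lost"
    )
    if (identical(res, "closed")) {
      closed_from <- t
      break
    }
    if (identical(res, "lost")) {
      warn(sprintf("tracking lost at frame %d; series truncated.", t))
      break
    }
    rows[[t]] <- dplyr::mutate(res, frame = t, time_min = (t - 1) * dt_min,
                               status = "tracked")
    prior <- res
  }
  out <- dplyr::bind_rows(rows)
  if (!is.na(closed_from)) {
    last <- out[nrow(out), ]
    closed <- tibble(
      cx_um = last$cx_um, cy_um = last$cy_um, radius_um = 0,
      diameter_um = 0, quality = NA_real_,
      frame = closed_from:nT, time_min = (closed_from:nT - 1) * dt_min,
      status = "closed"
    )
    out <- dplyr::bind_rows(out, closed)
  }
  out <- dplyr::relocate(out, "frame", "time_min")
  t0_index <- if (t0_convention == "onset") {
    hit <- which(abs(out$diameter_um - onset_um) <= onset_tol_um)
    if (length(hit) == 0L) {
      inform("no frame within the onset diameter window; t0 set to frame 1.")
      1L
    } else hit[1L]
  } else 1L
  structure(out,
            class = c("diameter_series", class(out)),
            t0_index = t0_index,
            pixel_size_um = pixel_size_um,
            frame_interval_s = frame_interval_s)
}

#' Closure velocity over fixed time steps
#'
#' Computes constriction velocities from non-overlapping diameter
#' differences over `step_min`-minute steps starting at the series' `t0`:
#' `v_k = (D(t_k) - D(t_k + step)) / step`, positive during constriction.
#' The summary velocity (attribute `mean_velocity_um_per_min`) averages the
#' steps completed before closure.
#'
#' @param series a [diameter_series()] tibble.
#' @param step_min step length in minutes (30 by default).
#' @return A tibble with `step`, `t_start_min`, `t_end_min`,
#'   `velocity_um_per_min`, and attribute `mean_velocity_um_per_min`.
#' @export
closure_velocity <- function(series, step_min = 30) {
  t0_index <- attr(series, "t0_index") %||% 1L
  dat <- series[t0_index:nrow(series), ]
  tt <- dat$time_min - dat$time_min[1]
  if (max(tt) < step_min) abort("series shorter than one velocity step.")
  dt <- stats::median(diff(tt))
  n_steps <- floor(max(tt) / step_min)
  grab <- function(target) {
    i <- which.min(abs(tt - target))
    if (abs(tt[i] - target) > dt / 2 + 1e-9) return(NA_real_)
    dat$diameter_um[i]
  }
  out <- purrr::map_dfr(seq_len(n_steps), function(k) {
    t_start <- (k - 1) * step_min
    t_end <- k * step_min
    d0 <- grab(t_start)
    d1 <- grab(t_end)
    tibble(step = k, t_start_min = t_start, t_end_min = t_end,
           velocity_um_per_min = (d0 - d1) / step_min)
  })
  closed_at <- dat$time_min[match("closed", dat$status)] - dat$time_min[1]
  pre <- if (is.na(closed_at)) out else
    out[out$t_end_min <= closed_at, , drop = FALSE]
  structure(out,
            mean_velocity_um_per_min = mean(pre$velocity_um_per_min, na.rm = TRUE))
}

#' Time of wound closure
#'
#' Returns the time (minutes from the series' `t0`) at which the wound
#' closes, or `NA` when it never does. The crossing of the closure
#' threshold (diameter equivalent of a 2 px radius by default) is refined
#' by extrapolating the final linear diameter trend to zero, since the ring
#' becomes untrackable a little before true closure.
#'
#' @param series a [diameter_series()] tibble.
#' @param threshold_um closure threshold on the diameter (um); default
#'   4 pixels (a 2 px radius).
#' @param extrapolate_points number of trailing pre-threshold points used
#'   for the linear extrapolation.
#' @return Closure time in minutes (scalar), or `NA_real_` if not closed.
#' @export
closure_time <- function(series, threshold_um = NULL,
                         extrapolate_points = 5L) {
  ps <- attr(series, "pixel_size_um")
  threshold_um <- threshold_um %||% (4 * ps)
  t0_index <- attr(series, "t0_index") %||% 1L
  dat <- series[t0_index:nrow(series), ]
  below <- which(dat$diameter_um <= threshold_um)
  if (length(below) == 0L) return(NA_real_)
  first_below <- below[1L]
  if (first_below == 1L) return(0)
  t_rel <- dat$time_min - dat$time_min[1]
  lo <- max(1L, first_below - extrapolate_points)
  idx <- lo:(first_below - 1L)
  idx <- idx[dat$diameter_um[idx] > threshold_um]
  if (length(idx) >= 2L) {
    fit <- stats::lm(d ~ t, data = data.frame(t = t_rel[idx],
                                              d = dat$diameter_um[idx]))
    a <- stats::coef(fit)[["t"]]
    b <- stats::coef(fit)[["(Intercept)"]]
    if (is.finite(a) && a < 0) {
      tc <- -b / a
      if (tc >= t_rel[idx[length(idx)]]) return(unname(tc))
    }
  }
  t_rel[first_below]
}
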