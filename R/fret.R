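#' Ratiometric FRET activity map
#'
#' Per-pixel donor/acceptor ratio with low-intensity pixels masked to `NA`
#' (and thereby excluded from every downstream mean). The default floor is
#' the 5th percentile of the acceptor channel. The donor/acceptor
#' orientation can be inverted for sensors with the opposite convention.
#'
#' @param donor,acceptor co-registered numeric matrices of equal shape.
#' @param floor intensity floor on the acceptor channel; pixels below it
#'   are masked.
#' @param invert if `TRUE`, compute acceptor/donor instead.
#' @return A numeric matrix of ratios with `NA` at masked pixels.
#' @export
ratio_map <- function(donor, acceptor, floor = NULL, invert = FALSE) {
  if (!identical(dim(donor), dim(acceptor))) {
    abort("donor and acceptor images must have the same shape.")
  }
  floor <- floor %||% stats::quantile(acceptor, 0.05, names = FALSE)
  r <- if (invert) acceptor / donor else donor / acceptor
  r[acceptor < floor | acceptor <= 0] <- NA_real_
  r
}

#' Slice the ring perimeter into normalized sections
#'
#' Tiles the ring perimeter into sections of `arc_len_um` of arc by
#' `depth_um` of radial depth centred on the cable, and measures each
#' section's mean myosin density and RhoA activity (ratio), each
#' normalized by the frame's ring average so the per-frame mean of
#' normalized values is 1. Sections within `assign_radius_um` of arc of a
#' classified cluster track are labelled by the track's class, the rest
#' `"cable"`.
#'
#' @param ratio_image ratio matrix from [ratio_map()] (may contain `NA`).
#' @param myosin_image myosin-channel matrix, same shape.
#' @param geometry one-row tibble/list with `frame`, `cx_um`, `cy_um`,
#'   `radius_um`.
#' @param pixel_size_um pixel size (um/px).
#' @param tracks optional [filter_and_classify()] tibble used for section
#'   labels.
#' @param arc_len_um,depth_um section size along and across the cable (um);
#'   defaults 1 x 0.5.
#' @param assign_radius_um cluster-to-section assignment distance (um of
#'   arc).
#' @return A tibble with `frame`, `section`, `angle_rad`, `arc_center_um`,
#'   `myosin_density_norm`, `rhoa_activity_norm`, `label`.
#' @export
section_ring <- function(ratio_image, myosin_image, geometry, pixel_size_um,
                         tracks = NULL, arc_len_um = 1, depth_um = 0.5,
                         assign_radius_um = 1) {
  if (!identical(dim(ratio_image), dim(myosin_image))) {
    abort("ratio and myosin images must have the same shape.")
  }
  R <- geometry$radius_um
  per <- 2 * pi * R
  n_sec <- floor(per / arc_len_um)
  if (n_sec < 1L) abort("perimeter shorter than one section.")
  dth <- 2 * pi / n_sec
  frame_id <- if (!is.null(geometry$frame)) geometry$frame[1] else 1L

  step <- pixel_size_um / 2
  radii <- seq(R - depth_um / 2, R + depth_um / 2, by = step)
  n_sub <- max(2L, ceiling((per / n_sec) / step))
  sec_means <- function(img) {
    vapply(seq_len(n_sec), function(j) {
      th <- (j - 1) * dth + (seq_len(n_sub) - 0.5) * dth / n_sub
      xg <- geometry$cx_um + outer(radii, cos(th))
      yg <- geometry$cy_um + outer(radii, sin(th))
      v <- bilinear_sample(img, as.numeric(xg), as.numeric(yg), pixel_size_um)
      mean(v, na.rm = TRUE)
    }, numeric(1))
  }
  myo <- sec_means(myosin_image)
  rho <- sec_means(ratio_image)
  theta_c <- ((seq_len(n_sec)) - 0.5) * dth

  label <- rep("cable", n_sec)
  if (!is.null(tracks) && nrow(tracks) > 0L) {
    tr <- as_tibble(tracks)
    tr <- tr[tr$frame == frame_id & !is.na(tr$class), , drop = FALSE]
    if (nrow(tr) > 0L) {
      for (j in seq_len(n_sec)) {
        d <- R * abs(angle_diff(tr$angle_rad, theta_c[j]))
        i <- which.min(d)
        if (d[i] <= assign_radius_um) label[j] <- tr$class[i]
      }
    }
  }
  tibble(
    frame = frame_id,
    section = seq_len(n_sec),
    angle_rad = theta_c,
    arc_center_um = R * theta_c,
    myosin_density_norm = myo / mean(myo, na.rm = TRUE),
    rhoa_activity_norm = rho / mean(rho, na.rm = TRUE),
    label = label
  )
}

#' RhoA activity as a function of myosin density
#'
#' Bins ring sections by normalized myosin density and reports the mean
#' and standard error of normalized RhoA activity per bin, together with
#' per-label (radial / tangential / cable) summaries.
#'
#' @param sections tibble from [section_ring()] (rows from several frames
#'   may be concatenated); needs >= 20 sections.
#' @param n_bins number of equal-width density bins.
#' @return A list of class `activity_density`: `curve` (tibble with
#'   `bin_mid`, `n`, `mean_rhoa`, `se_rhoa`) and `by_label` (tibble with
#'   `label`, `n`, `mean_myosin`, `mean_rhoa`, `se_rhoa`).
#' @export
activity_vs_density <- function(sections, n_bins = 8L) {
  dat <- as_tibble(sections)
  dat <- dat[is.finite(dat$myosin_density_norm) &
               is.finite(dat$rhoa_activity_norm), , drop = FALSE]
  if (nrow(dat) < 20L) abort("need at least 20 sections.")
  brks <- seq(min(dat$myosin_density_norm), max(dat$myosin_density_norm),
              length.out = n_bins + 1L)
  brks[1] <- brks[1] - 1e-9
  dat$bin <- cut(dat$myosin_density_norm, brks, labels = FALSE)
  curve <- dat |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(
      bin_mid = (brks[.data$bin[1]] + brks[.data$bin[1] + 1L]) / 2,
      n = dplyr::n(),
      mean_rhoa = mean(.data$rhoa_activity_norm),
      se_rhoa = stats::sd(.data$rhoa_activity_norm) / sqrt(dplyr::n()),
      .groups = "drop")
  by_label <- dat |>
    dplyr::group_by(.data$label) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_myosin = mean(.data$myosin_density_norm),
      mean_rhoa = mean(.data$rhoa_activity_norm),
      se_rhoa = stats::sd(.data$rhoa_activity_norm) / sqrt(dplyr::n()),
      .groups = "drop")
  missing <- setdiff(c("radial", "tangential", "cable"), by_label$label)
  if (length(missing)) {
    inform(paste("empty label groups:", paste(missing, collapse = ", ")))
  }
  structure(list(curve = curve, by_label = by_label),
            class = "activity_density")
}

#' Peak lag between RhoA activity and myosin density
#'
#' Smooths both series with a centred moving average, locates each peak by
#' argmax with parabolic sub-sample refinement, and returns
#' `lag = myosin peak - RhoA peak` (positive when RhoA leads). A peak
#' sitting on the first or last sample is flagged unreliable.
#'
#' @param data data frame with columns `time_min`, `rhoa`, `myosin`
#'   sharing one time base (e.g. from [simulate_burst_series()]).
#' @param smooth_window_min moving-average window (min).
#' @return One-row tibble: `rhoa_peak_min`, `myosin_peak_min`, `lag_min`,
#'   `reliable`.
#' @export
peak_lag <- function(data, smooth_window_min = 3) {
  dat <- as_tibble(data)
  if (!all(c("time_min", "rhoa", "myosin") %in% names(dat))) {
    abort("`data` needs columns time_min, rhoa, myosin.")
  }
  dt <- stats::median(diff(dat$time_min))
  w <- max(1L, round(smooth_window_min / dt))
  find_peak <- function(x) {
    s <- moving_average(x, w)
    i <- which.max(s)
    at_edge <- i == 1L || i == length(s)
    off <- if (at_edge) 0 else parabolic_offset(s[i - 1L], s[i], s[i + 1L])
    list(t = dat$time_min[1] + (i - 1 + off) * dt, edge = at_edge)
  }
  pr <- find_peak(dat$rhoa)
  pm <- find_peak(dat$myosin)
  if (pr$edge || pm$edge) {
    warn("peak at series boundary; lag estimate unreliable.")
  }
  tibble(
    rhoa_peak_min = pr$t,
    myosin_peak_min = pm$t,
    lag_min = pm$t - pr$t,
    reliable = !(pr$edge || pm$edge)
  )
}
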