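#' Simulate paired RhoA-activity / myosin-density burst series
#'
#' One-dimensional analogue of the post-ablation response: after laser
#' ablation the cable reforms with a transient burst of RhoA activity
#' followed, `lag_min` minutes later, by a burst of myosin density. Both
#' bursts are Gaussian in time on a flat baseline, with optional additive
#' noise parameterized by the signal-to-noise ratio (burst amplitude over
#' noise sd).
#'
#' @param duration_min series duration (min).
#' @param dt_min sampling interval (min).
#' @param rhoa_peak_min time of the RhoA activity peak (min).
#' @param lag_min myosin peak delay after the RhoA peak (min, >= 0).
#' @param width_min Gaussian sd of both bursts (min).
#' @param amplitude burst amplitude over baseline (a.u.).
#' @param baseline baseline level (a.u.).
#' @param snr burst amplitude / noise sd; `Inf` for noiseless.
#' @param seed integer seed; `NULL` uses the current stream.
#' @return A tibble with columns `time_min`, `rhoa`, `myosin`; attributes
#'   `rhoa_peak_min`, `myosin_peak_min`, `lag_min` hold the ground truth.
#' @examples
#' b <- simulate_burst_series(lag_min = 4, snr = Inf)
#' attr(b, "lag_min")
#' @export
simulate_burst_series <- function(duration_min = 30,
                                  dt_min = 1,
                                  rhoa_peak_min = 8,
                                  lag_min = 4,
                                  width_min = 3,
                                  amplitude = 1,
                                  baseline = 1,
                                  snr = 5,
                                  seed = NULL) {
  if (lag_min < 0) abort("`lag_min` must be >= 0.")
  stopifnot_scalar_pos(width_min, "width_min")
  myosin_peak_min <- rhoa_peak_min + lag_min
  if (myosin_peak_min + 2 * width_min > duration_min ||
      rhoa_peak_min - 2 * width_min < 0) {
    abort("burst extends beyond the series.")
  }
  times <- seq(0, duration_min, by = dt_min)
  rhoa <- baseline + amplitude * exp(-(times - rhoa_peak_min)^2 / (2 * width_min^2))
  myosin <- baseline + amplitude * exp(-(times - myosin_peak_min)^2 / (2 * width_min^2))
  if (is.finite(snr)) {
    if (snr <= 0) abort("`snr` must be > 0.")
    sd <- amplitude / snr
    noise <- with_seed(seed, stats::rnorm(2L * length(times), sd = sd))
    rhoa <- rhoa + noise[seq_along(times)]
    myosin <- myosin + noise[length(times) + seq_along(times)]
  }
  structure(tibble(time_min = times, rhoa = rhoa, myosin = myosin),
            rhoa_peak_min = rhoa_peak_min,
            myosin_peak_min = myosin_peak_min,
            lag_min = lag_min)
}

#' Simulate a donor/acceptor FRET + myosin movie around an ablation
#'
#' Renders three co-registered stacks: FRET donor, FRET acceptor and a
#' myosin channel. The donor/acceptor ratio is elevated on the actomyosin
#' cable by `rhoa_gain`; after the ablation frame, the cable-averaged RhoA
#' ratio and myosin density follow Gaussian temporal bursts whose peaks are
#' separated by exactly `lag_min` minutes (myosin later), emulating the
#' observation that RhoA activation precedes myosin recruitment during
#' cable reformation.
#'
#' @param config a [sim_config()]; the myosin channel is rendered from it.
#' @param ablation_frame frame index of the simulated ablation.
#' @param lag_min myosin-after-RhoA peak delay (min, >= 0).
#' @param burst_width_min Gaussian sd of the temporal bursts (min).
#' @param rise_min delay from ablation to the RhoA peak (min).
#' @param rhoa_gain cable ratio elevation factor over the background
#'   ratio of 1.
#' @param burst_amplitude fractional modulation of cable RhoA gain and
#'   cable myosin enrichment at burst peak.
#' @param acceptor_intensity uniform acceptor-channel level (a.u.).
#' @return A list of class `fret_movie`: `donor`, `acceptor`, `myosin`
#'   (arrays `[rows, cols, frames]`), `config`, and `truth` (geometry tibble
#'   plus `rhoa_peak_min`, `myosin_peak_min`, `lag_min`).
#' @export
simulate_fret_sequence <- function(config,
                                   ablation_frame = 3L,
                                   lag_min = 4,
                                   burst_width_min = 3,
                                   rise_min = 6,
                                   rhoa_gain = 1.8,
                                   burst_amplitude = 0.5,
                                   acceptor_intensity = 200) {
  if (!inherits(config, "sim_config")) abort("`config` must be a sim_config.")
  if (lag_min < 0) abort("`lag_min` must be >= 0.")
  dt_min <- config$frame_interval_s / 60
  times_min <- (seq_len(config$n_frames) - 1) * dt_min
  t_abl <- (ablation_frame - 1) * dt_min
  rhoa_peak_min <- t_abl + rise_min
  myosin_peak_min <- rhoa_peak_min + lag_min
  if (myosin_peak_min + 2 * burst_width_min > max(times_min)) {
    abort("burst extends beyond the movie.")
  }

  with_seed(config$seed, {
    R0 <- config$ring_diameter0_um / 2
    radii <- pmax(R0 - (config$closure_velocity_um_per_min / 2) * times_min, 0)
    center <- c(config$image_size_px[2], config$image_size_px[1]) *
      config$pixel_size_um / 2
    nr <- config$image_size_px[1]
    nc <- config$image_size_px[2]
    xs <- (seq_len(nc) - 0.5) * config$pixel_size_um
    ys <- (seq_len(nr) - 0.5) * config$pixel_size_um
    xmat <- matrix(xs, nr, nc, byrow = TRUE)
    ymat <- matrix(ys, nr, nc)
    rmat <- sqrt((xmat - center[1])^2 + (ymat - center[2])^2)

    burst <- function(t, peak) exp(-(t - peak)^2 / (2 * burst_width_min^2))
    dims <- c(nr, nc, config$n_frames)
    donor <- array(0, dims)
    acceptor <- array(0, dims)
    myosin <- array(0, dims)
    for (t in seq_len(config$n_frames)) {
      tube <- exp(-(rmat - radii[t])^2 / (2 * config$cable_width_um^2))
      post <- times_min[t] >= t_abl
      g_t <- 1 + (rhoa_gain - 1) *
        (1 + if (post) burst_amplitude * burst(times_min[t], rhoa_peak_min) else 0)
      enr_t <- 1 + (config$cable_enrichment - 1) *
        (1 + if (post) burst_amplitude * burst(times_min[t], myosin_peak_min) else 0)
      ratio_field <- 1 + (g_t - 1) * tube
      acc <- matrix(acceptor_intensity, nr, nc)
      don <- acc * ratio_field
      myo <- config$base_intensity * (1 + (enr_t - 1) * tube)
      if (config$gaussian_sd > 0) {
        acc <- acc + stats::rnorm(length(acc), sd = config$gaussian_sd)
        don <- don + stats::rnorm(length(don), sd = config$gaussian_sd)
        myo <- myo + stats::rnorm(length(myo), sd = config$gaussian_sd)
      }
      donor[, , t] <- don
      acceptor[, , t] <- acc
      myosin[, , t] <- myo
    }
    geometry <- tibble(
      frame = seq_len(config$n_frames),
      time_min = times_min,
      cx_um = center[1], cy_um = center[2],
      radius_um = radii
    )
    structure(list(
      donor = donor, acceptor = acceptor, myosin = myosin, config = config,
      truth = list(geometry = geometry,
                   rhoa_peak_min = rhoa_peak_min,
                   myosin_peak_min = myosin_peak_min,
                   lag_min = lag_min)
    ), class = "fret_movie")
  })
}
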