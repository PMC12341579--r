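#' @importFrom ggplot2 autoplot ggplot aes geom_raster geom_line geom_point
#'   geom_errorbar labs scale_fill_viridis_c theme_minimal
NULL

#' @export
ggplot2::autoplot

#' Plot a kymograph as an angle-time heat map
#'
#' @param object a [build_kymograph()] object.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.kymograph <- function(object, ...) {
  dt_min <- object$frame_interval_s / 60
  df <- tidyr::expand_grid(bin = seq_len(nrow(object$values)),
                           frame = seq_len(ncol(object$values)))
  df$intensity <- object$values[cbind(df$bin, df$frame)]
  df$angle_rad <- object$angle_rad[df$bin]
  df$time_min <- (df$frame - 1) * dt_min
  ggplot(df, aes(x = .data$time_min, y = .data$angle_rad,
                 fill = .data$intensity)) +
    geom_raster() +
    scale_fill_viridis_c(name = "intensity (a.u.)") +
    labs(x = "time (min)", y = "angle (rad)",
         title = "Circumferential kymograph") +
    theme_minimal()
}

#' Plot a diameter series
#'
#' @param object a [diameter_series()] tibble.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.diameter_series <- function(object, ...) {
  ggplot(as_tibble(object),
         aes(x = .data$time_min, y = .data$diameter_um)) +
    geom_line() +
    labs(x = "time (min)", y = "wound diameter (µm)",
         title = "Wound constriction") +
    theme_minimal()
}

#' Plot a recoil fit with its data
#'
#' @param object a [fit_retraction()] object.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.retraction_fit <- function(object, ...) {
  dat <- object$data
  grid <- tibble(
    time_s = seq(min(dat$time_s), max(dat$time_s), length.out = 200)
  )
  grid$length_um <- object$t0_over_zeta_um_per_s * object$tau_s *
    (1 - exp(-grid$time_s / object$tau_s))
  ggplot(dat, aes(x = .data$time_s, y = .data$length_um)) +
    geom_point() +
    geom_line(data = grid, colour = "firebrick") +
    labs(x = "time post-ablation (s)", y = "retracted length (µm)",
         title = sprintf("Recoil fit: T0/ζ = %.2f µm/s, τ = %.1f s",
                         object$t0_over_zeta_um_per_s, object$tau_s)) +
    theme_minimal()
}

#' Plot RhoA activity vs myosin density
#'
#' @param object an [activity_vs_density()] object.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.activity_density <- function(object, ...) {
  ggplot(object$curve, aes(x = .data$bin_mid, y = .data$mean_rhoa)) +
    geom_errorbar(aes(ymin = .data$mean_rhoa - .data$se_rhoa,
                      ymax = .data$mean_rhoa + .data$se_rhoa), width = 0) +
    geom_point() +
    geom_line() +
    labs(x = "myosin density (ring-normalized)",
         y = "RhoA activity (ring-normalized)",
         title = "RhoA activity vs myosin density") +
    theme_minimal()
}
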