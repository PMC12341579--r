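#' Build a retraction trace from front coordinates
#'
#' Converts tracked positions of the two retracting cable fronts into the
#' retracted length vs time: the Euclidean distance between the fronts
#' minus the initial cut length, clamped at zero.
#'
#' @param front_a,front_b per-timepoint front positions: two-column
#'   matrices / data frames (x, y in um) or numeric vectors (1-D
#'   positions).
#' @param times_s sample times (s), same length as the position lists.
#' @param cut_length_um initial cut length subtracted from the distances;
#'   defaults to the first-sample distance.
#' @param cluster_class label carried on the trace (`"radial"`,
#'   `"tangential"` or `"none"`).
#' @return A `retraction_trace` tibble (`time_s`, `length_um`,
#'   `cluster_class`).
#' @export
measure_retraction <- function(front_a, front_b, times_s,
                               cut_length_um = NULL,
                               cluster_class = "none") {
  pos <- function(p) {
    if (is.null(dim(p))) cbind(as.numeric(p), 0)
    else as.matrix(p)[, 1:2, drop = FALSE]
  }
  a <- pos(front_a)
  b <- pos(front_b)
  if (nrow(a) != nrow(b) || nrow(a) != length(times_s)) {
    abort("front positions and times must have equal length.")
  }
  d <- sqrt(rowSums((a - b)^2))
  cut <- cut_length_um %||% d[1]
  out <- tibble(time_s = as.numeric(times_s),
                length_um = pmax(d - cut, 0),
                cluster_class = cluster_class)
  structure(out, class = c("retraction_trace", class(out)))
}

#' Fit the viscoelastic recoil model to a retraction trace
#'
#' Least-squares fit of the integrated recoil model
#' `L(t) = (T0/zeta) * tau * (1 - exp(-t / tau))`, the time integral of the
#' exponentially decaying front velocity `v(t) = (T0/zeta) * exp(-t/tau)`.
#' `T0/zeta` -- pre-ablation tension over damping -- equals the initial
#' recoil velocity. Fitting the integrated length rather than the
#' differentiated velocity avoids amplifying sampling noise. Starting
#' values come from the first finite difference (velocity) and a
#' log-linearised tail (tau); parameters are bounded to `T0/zeta >= 0`,
#' `tau` in (0.1, 300) s.
#'
#' @param trace a `retraction_trace` or any data frame with `time_s` and
#'   `length_um`; needs >= 4 samples spanning at least twice the sample
#'   interval.
#' @return An object of class `retraction_fit` with elements
#'   `t0_over_zeta_um_per_s`, `tau_s`, `residual_rms_um`, `cov`
#'   (2 x 2 covariance of the estimates), `n`, `data`. Supports
#'   [tidy()], [glance()] and [ggplot2::autoplot()].
#' @export
fit_retraction <- function(trace) {
  dat <- as_tibble(trace)
  if (!all(c("time_s", "length_um") %in% names(dat))) {
    abort("`trace` needs columns `time_s` and `length_um`.")
  }
  dat <- dplyr::arrange(dat, .data$time_s)
  n <- nrow(dat)
  if (n < 4L) abort("need at least 4 samples to fit the recoil model.")
  dt <- stats::median(diff(dat$time_s))
  if (diff(range(dat$time_s)) < 2 * dt) {
    abort("trace must span at least twice the sample interval.")
  }
  t <- dat$time_s
  L <- dat$length_um
  v0 <- max((L[2] - L[1]) / (t[2] - t[1]), 1e-6)
  tau0 <- init_tau(t, L)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      L ~ v * tau * (1 - exp(-t / tau)),
      data = data.frame(t = t, L = L),
      start = list(v = v0, tau = tau0),
      lower = c(v = 0, tau = 0.1),
      upper = c(v = Inf, tau = 300),
      control = minpack.lm::nls.lm.control(
        maxiter = 200, ftol = 1e-14, ptol = 1e-14)
    ),
    error = function(e) {
      abort(paste0("recoil fit did not converge: ", conditionMessage(e)),
            class = "woundring_fit_failed")
    }
  )
  co <- stats::coef(fit)
  vc <- tryCatch(stats::vcov(fit), error = function(e) matrix(NA_real_, 2, 2))
  structure(list(
    t0_over_zeta_um_per_s = unname(co[["v"]]),
    tau_s = unname(co[["tau"]]),
    residual_rms_um = sqrt(mean(stats::residuals(fit)^2)),
    cov = vc,
    n = n,
    data = dat,
    fit = fit
  ), class = "retraction_fit")
}

# tau starting value from the log-linearised tail:
# log(1 - L / Linf) = -t / tau with Linf slightly above max(L).
init_tau <- function(t, L) {
  span <- diff(range(t))
  Linf <- max(L) * 1.05
  y <- 1 - L / Linf
  ok <- y > 1e-6 & t > 0
  if (sum(ok) >= 2L) {
    sl <- stats::coef(stats::lm(log(y[ok]) ~ t[ok]))[2]
    if (is.finite(sl) && sl < 0) return(min(max(-1 / sl, 0.1), 300))
  }
  min(max(span / 3, 0.1), 300)
}

#' @export
print.retraction_fit <- function(x, ...) {
  cat("Viscoelastic recoil fit  L(t) = (T0/zeta) tau (1 - exp(-t/tau))\n")
  cat(sprintf("  T0/zeta (initial velocity): %.4g um/s\n",
              x$t0_over_zeta_um_per_s))
  cat(sprintf("  tau:                        %.4g s\n", x$tau_s))
  cat(sprintf("  residual RMS: %.3g um over %d samples\n",
              x$residual_rms_um, x$n))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.retraction_fit <- function(x, ...) {
  se <- sqrt(diag(x$cov))
  tibble(
    term = c("t0_over_zeta_um_per_s", "tau_s"),
    estimate = c(x$t0_over_zeta_um_per_s, x$tau_s),
    std.error = as.numeric(se)
  )
}

#' @export
glance.retraction_fit <- function(x, ...) {
  tibble(
    t0_over_zeta_um_per_s = x$t0_over_zeta_um_per_s,
    tau_s = x$tau_s,
    residual_rms_um = x$residual_rms_um,
    nobs = x$n
  )
}

#' Initial recoil velocity by finite differences
#'
#' Slope of the retracted length over the first `n_points` samples: the
#' two-point finite difference by default (matching velocities read
#' between the first post-ablation timepoints), or the least-squares slope
#' through the first `n_points` samples.
#'
#' @param trace a `retraction_trace` or data frame with `time_s`,
#'   `length_um`.
#' @param n_points number of leading samples used (>= 2).
#' @return Velocity in um/s (scalar).
#' @export
initial_velocity <- function(trace, n_points = 2L) {
  dat <- dplyr::arrange(as_tibble(trace), .data$time_s)
  n_points <- max(2L, as.integer(n_points))
  if (nrow(dat) < n_points) abort("trace has fewer samples than `n_points`.")
  t <- dat$time_s[seq_len(n_points)]
  L <- dat$length_um[seq_len(n_points)]
  if (anyDuplicated(t)) abort("duplicate timestamps in trace.")
  if (n_points == 2L) {
    (L[2] - L[1]) / (t[2] - t[1])
  } else {
    unname(stats::coef(stats::lm(L ~ t))[2])
  }
}

#' Tension ratio between two recoil groups
#'
#' Ratio of group-mean initial recoil velocities `T0/zeta`. Assuming equal
#' damping `zeta` along the cable, this ratio reads out the ratio of
#' pre-ablation tensions between the two groups (e.g. radial vs tangential
#' clusters). Uncertainty by seeded percentile bootstrap over traces.
#'
#' @param fits_a,fits_b the two groups: lists of [fit_retraction()]
#'   objects, numeric vectors of velocities, or data frames with a
#'   `t0_over_zeta_um_per_s` column.
#' @param n_boot bootstrap resamples (2000 by default).
#' @param conf confidence level of the percentile interval.
#' @param seed integer seed for the bootstrap.
#' @return One-row tibble: `ratio`, `ci_lower`, `ci_upper`, `n_a`, `n_b`.
#' @export
tension_ratio <- function(fits_a, fits_b, n_boot = 2000L, conf = 0.95,
                          seed = 1L) {
  va <- extract_velocities(fits_a)
  vb <- extract_velocities(fits_b)
  if (length(va) == 0L || length(vb) == 0L) abort("both groups must be nonempty.")
  if (abs(mean(vb)) < .Machine$double.eps) abort("denominator group mean is zero.")
  ratio <- mean(va) / mean(vb)
  boots <- with_seed(seed, {
    vapply(seq_len(n_boot), function(i) {
      mean(sample(va, replace = TRUE)) / mean(sample(vb, replace = TRUE))
    }, numeric(1))
  })
  alpha <- (1 - conf) / 2
  qs <- stats::quantile(boots, c(alpha, 1 - alpha), names = FALSE)
  tibble(ratio = ratio, ci_lower = qs[1], ci_upper = qs[2],
         n_a = length(va), n_b = length(vb))
}

extract_velocities <- function(x) {
  if (is.numeric(x)) return(as.numeric(x))
  if (inherits(x, "retraction_fit")) return(x$t0_over_zeta_um_per_s)
  if (is.data.frame(x)) return(as.numeric(x$t0_over_zeta_um_per_s))
  if (is.list(x)) {
    return(vapply(x, function(f) f$t0_over_zeta_um_per_s, numeric(1)))
  }
  abort("cannot extract recoil velocities from this object.")
}
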