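#' Simulate a post-ablation cable retraction trace
#'
#' Generates the retracted length between severed cable fronts under the
#' active viscoelastic recoil model: the front velocity decays as
#' `v(t) = (T0/zeta) * exp(-t / tau)`, so the retracted length is
#' `L(t) = (T0/zeta) * tau * (1 - exp(-t / tau))`. `T0/zeta` (tension over
#' damping) equals the initial recoil velocity; `tau` is the viscoelastic
#' relaxation time.
#'
#' @param t0_over_zeta_um_per_s initial recoil velocity `T0/zeta` (um/s).
#' @param tau_s relaxation time (s), > 0.
#' @param times_s sample times (s), strictly increasing from 0. The default
#'   matches a 1.2 s imaging interval over 30 s.
#' @param noise_sd_um sd of additive Gaussian noise per sample (um); >= 0.
#' @param cluster_class optional label carried through to the trace
#'   (`"radial"`, `"tangential"` or `"none"`).
#' @param seed integer seed for the noise; `NULL` uses the current stream.
#' @return A tibble of class `retraction_trace` with columns `time_s`,
#'   `length_um`, `cluster_class`, and attributes `true_t0_over_zeta`,
#'   `true_tau_s`, `noise_sd_um`.
#' @examples
#' tr <- simulate_retraction_trace(6.2, tau_s = 5)
#' head(tr)
#' @export
simulate_retraction_trace <- function(t0_over_zeta_um_per_s,
                                      tau_s,
                                      times_s = seq(0, 30, by = 1.2),
                                      noise_sd_um = 0,
                                      cluster_class = "none",
                                      seed = NULL) {
  stopifnot_scalar_pos(tau_s, "tau_s")
  if (t0_over_zeta_um_per_s < 0) abort("`t0_over_zeta_um_per_s` must be >= 0.")
  if (noise_sd_um < 0) abort("`noise_sd_um` must be >= 0.")
  if (length(times_s) < 2L || times_s[1] < 0 || any(diff(times_s) <= 0)) {
    abort("`times_s` must be nonnegative and strictly increasing.")
  }
  lengths <- t0_over_zeta_um_per_s * tau_s * (1 - exp(-times_s / tau_s))
  if (noise_sd_um > 0) {
    noise <- with_seed(seed, stats::rnorm(length(times_s), sd = noise_sd_um))
    lengths <- lengths + noise
  }
  out <- tibble(
    time_s = times_s,
    length_um = lengths,
    cluster_class = cluster_class
  )
  structure(out,
            class = c("retraction_trace", class(out)),
            true_t0_over_zeta = t0_over_zeta_um_per_s,
            true_tau_s = tau_s,
            noise_sd_um = noise_sd_um)
}
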