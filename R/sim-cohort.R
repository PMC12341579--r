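#' Simulate a wound cohort linking radial-cluster fraction to closure speed
#'
#' Generates a cohort table with the statistical structure of the
#' radial-fraction / closure-velocity relationship: each wound draws a
#' radial cluster fraction uniformly on [0, 1] and a closure velocity
#' `intercept + slope * radial_fraction + noise`. Exactly one of `noise_sd`
#' and `target_r` must be supplied; with `target_r`, the noise sd is solved
#' analytically so the *population* Pearson correlation equals `target_r`
#' given the uniform fraction spread:
#' `noise_sd = |slope| * sd(fraction) * sqrt(1 / r^2 - 1)`.
#'
#' @param n number of wounds (>= 3).
#' @param slope velocity change per unit radial fraction (um/min).
#' @param intercept velocity at zero radial fraction (um/min).
#' @param noise_sd sd of the additive velocity noise (um/min).
#' @param target_r desired population correlation, in (0, 1].
#' @param seed integer seed; `NULL` uses the current stream.
#' @return A tibble with columns `wound_id`, `radial_fraction`,
#'   `closure_velocity_um_min`, `n_clusters`.
#' @examples
#' co <- simulate_cohort(25, target_r = 0.8, seed = 1)
#' cor(co$radial_fraction, co$closure_velocity_um_min)
#' @export
simulate_cohort <- function(n,
                            slope = 0.15,
                            intercept = 0.05,
                            noise_sd = NULL,
                            target_r = NULL,
                            seed = NULL) {
  if (n < 3) abort("`n` must be >= 3.")
  if (is.null(noise_sd) == is.null(target_r)) {
    abort("supply exactly one of `noise_sd` and `target_r`.")
  }
  if (!is.null(target_r)) {
    if (target_r <= 0 || target_r > 1) {
      abort("`target_r` must lie in (0, 1].")
    }
    sd_x <- sqrt(1 / 12) # sd of U(0, 1)
    noise_sd <- abs(slope) * sd_x * sqrt(1 / target_r^2 - 1)
  }
  if (noise_sd < 0) abort("`noise_sd` must be >= 0.")
  with_seed(seed, {
    frac <- stats::runif(n)
    vel <- intercept + slope * frac +
      if (noise_sd > 0) stats::rnorm(n, sd = noise_sd) else 0
    tibble(
      wound_id = seq_len(n),
      radial_fraction = frac,
      closure_velocity_um_min = vel,
      n_clusters = pmax(1L, stats::rpois(n, lambda = 3))
    )
  })
}
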