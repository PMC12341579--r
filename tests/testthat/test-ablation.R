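test_that("measure_retraction turns front coordinates into lengths", {
  t <- seq(0, 5, by = 1)
  static <- measure_retraction(cbind(0, 0 * t), cbind(3, 0 * t), t)
  expect_true(all(static$length_um == 0))
  # fronts separating symmetrically at 1 um/s each -> slope 2 um/s
  sep <- measure_retraction(cbind(-t, 0), cbind(t, 0), t)
  expect_equal(sep$length_um, 2 * t)
  expect_error(measure_retraction(cbind(0, 0), cbind(c(0, 1), c(0, 0)),
                                  c(0, 1)), "equal length")
})

test_that("recoil fit recovers noiseless parameters to machine tolerance", {
  for (tau in c(0.5, 2, 5, 20, 50)) {
    tr <- simulate_retraction_trace(4.4, tau)
    f <- fit_retraction(tr)
    expect_lt(abs(f$t0_over_zeta_um_per_s - 4.4) / 4.4, 1e-6)
    expect_lt(abs(f$tau_s - tau) / tau, 1e-5)
  }
})

test_that("fit handles the linear (tau -> Inf) regime", {
  tr <- tibble::tibble(time_s = seq(0, 6, by = 1.2),
                       length_um = 2 * seq(0, 6, by = 1.2))
  f <- fit_retraction(tr)
  expect_equal(f$t0_over_zeta_um_per_s, 2, tolerance = 0.01)
})

test_that("fit rejects undersized traces and reports diagnostics", {
  expect_error(fit_retraction(tibble::tibble(time_s = 0:2,
                                             length_um = c(0, 1, 2))),
               "4 samples")
  f <- fit_retraction(simulate_retraction_trace(3.9, 5,
                                                noise_sd_um = 0.3, seed = 1))
  expect_true(all(is.finite(tidy(f)$std.error)))
  expect_equal(nrow(glance(f)), 1L)
})

test_that("recoil fit is median-unbiased under realistic noise", {
  est <- vapply(1:200, function(s) {
    tr <- simulate_retraction_trace(6.2, 5, noise_sd_um = 0.3, seed = s)
    fit_retraction(tr)$t0_over_zeta_um_per_s
  }, numeric(1))
  expect_lt(abs(stats::median(est) - 6.2) / 6.2, 0.05)
})

test_that("scale equivariance: lengths x c scale T0/zeta, not tau", {
  tr <- simulate_retraction_trace(2.5, 8, noise_sd_um = 0.1, seed = 3)
  f1 <- fit_retraction(tr)
  tr2 <- dplyr::mutate(tibble::as_tibble(tr), length_um = 3 * length_um)
  f2 <- fit_retraction(tr2)
  expect_equal(f2$t0_over_zeta_um_per_s, 3 * f1$t0_over_zeta_um_per_s,
               tolerance = 1e-6)
  expect_equal(f2$tau_s, f1$tau_s, tolerance = 1e-6)
})

test_that("initial velocity is the leading finite-difference slope", {
  tr <- tibble::tibble(time_s = c(0, 1.2, 2.4),
                       length_um = c(0, 7.44, 12))
  expect_equal(initial_velocity(tr), 6.2)
  flat <- tibble::tibble(time_s = 0:5, length_um = rep(1, 6))
  expect_equal(initial_velocity(flat), 0)
  expect_error(initial_velocity(tibble::tibble(time_s = c(0, 0),
                                               length_um = c(0, 1))),
               "duplicate")
  # slow decay: two-point estimate within the dt/(2 tau) expansion error
  tr2 <- simulate_retraction_trace(5, 50, times_s = seq(0, 12, 1.2))
  v <- initial_velocity(tr2)
  expect_lt(abs(v - 5) / 5, 0.15)
  expect_equal(abs(v - 5) / 5, 1.2 / (2 * 50), tolerance = 0.25)
})

test_that("tension ratio compares group means with bootstrap CI", {
  r <- tension_ratio(c(6.2, 6.2), c(3.9, 3.9), n_boot = 100)
  expect_equal(r$ratio, 6.2 / 3.9, tolerance = 1e-12)
  same <- tension_ratio(c(2, 3, 4), c(2, 3, 4), n_boot = 100)
  expect_equal(same$ratio, 1)
  expect_error(tension_ratio(numeric(0), 1:3), "nonempty")
  expect_error(tension_ratio(1:3, c(-1, 1)), "zero")
  # SEM-scaled synthetic groups: CI covers the 1.6 tension ratio
  va <- woundring:::with_seed(10, stats::rnorm(11, 6.2, 0.6 * sqrt(11)))
  vb <- woundring:::with_seed(11, stats::rnorm(8, 3.9, 0.4 * sqrt(8)))
  ci <- tension_ratio(va, vb, seed = 1)
  expect_lt(ci$ci_lower, 1.6)
  expect_gt(ci$ci_upper, 1.6)
})

test_that("fits accept traces measured from generator front geometry", {
  # build symmetric front coordinates whose separation follows L(t)
  tr <- simulate_retraction_trace(6.2, 5)
  half <- tr$length_um / 2
  meas <- measure_retraction(cbind(-half, 0), cbind(half, 0), tr$time_s)
  expect_equal(meas$length_um, tr$length_um, tolerance = 1e-12)
  f <- fit_retraction(meas)
  expect_equal(f$t0_over_zeta_um_per_s, 6.2, tolerance = 1e-6)
})
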