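# Internal geometry and numeric helpers shared across modules.
#
# Image convention: a frame is a numeric matrix indexed [row, col] with the
# pixel centre of frame[i, j] at physical coordinates
#   x = (j - 0.5) * pixel_size_um,  y = (i - 0.5) * pixel_size_um,
# x increasing along columns, y along rows. Angles are measured
# counter-clockwise from the +x axis in this (x, y) frame.

#' @importFrom rlang abort warn inform %||%
#' @importFrom tibble tibble as_tibble
NULL

# Evaluate RNG-consuming code under a caller-supplied seed without
# disturbing the global stream; seed = NULL leaves the stream alone.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Wrap angles into [0, 2*pi).
wrap_angle <- function(theta) theta %% (2 * pi)

# Signed smallest angular difference a - b, in (-pi, pi].
angle_diff <- function(a, b) {
  d <- (a - b) %% (2 * pi)
  d[d > pi] <- d[d > pi] - 2 * pi
  d
}

# Bilinear interpolation of img (matrix, [row, col]) at physical
# coordinates (x_um, y_um). Coordinates outside the frame are clamped to
# the border pixel centres.
bilinear_sample <- function(img, x_um, y_um, pixel_size_um) {
  nr <- nrow(img)
  nc <- ncol(img)
  cx <- pmin(pmax(x_um / pixel_size_um + 0.5, 1), nc) # fractional col
  cy <- pmin(pmax(y_um / pixel_size_um + 0.5, 1), nr) # fractional row
  j0 <- pmin(floor(cx), nc - 1L)
  i0 <- pmin(floor(cy), nr - 1L)
  fx <- cx - j0
  fy <- cy - i0
  idx <- function(i, j) img[cbind(i, j)]
  idx(i0, j0) * (1 - fx) * (1 - fy) +
    idx(i0, j0 + 1) * fx * (1 - fy) +
    idx(i0 + 1, j0) * (1 - fx) * fy +
    idx(i0 + 1, j0 + 1) * fx * fy
}

# Mean intensity sampled on circles of the given radii (um) about a
# centre, n_angles samples per circle. Returns one mean per radius;
# `fun` can replace the mean (e.g. for medians).
radial_profile <- function(img, center_um, radii_um, pixel_size_um,
                           n_angles = 360L) {
  theta <- seq(0, 2 * pi, length.out = n_angles + 1L)[-(n_angles + 1L)]
  ct <- cos(theta)
  st <- sin(theta)
  vapply(radii_um, function(r) {
    mean(bilinear_sample(img, center_um[1] + r * ct, center_um[2] + r * st,
                         pixel_size_um))
  }, numeric(1))
}

# Sub-grid refinement of a peak by fitting a parabola through the maximum
# and its two neighbours; returns the fractional offset in grid units,
# clamped to [-0.5, 0.5].
parabolic_offset <- function(ym1, y0, yp1) {
  denom <- ym1 - 2 * y0 + yp1
  if (!is.finite(denom) || abs(denom) < .Machine$double.eps) return(0)
  off <- 0.5 * (ym1 - yp1) / denom
  min(max(off, -0.5), 0.5)
}

# Circular convolution of x with a Gaussian kernel of sd `sigma` given in
# bin units; used to smooth circumferential profiles before peak finding.
circular_gaussian_smooth <- function(x, sigma) {
  n <- length(x)
  if (sigma <= 0 || n < 3) return(x)
  half <- min(ceiling(4 * sigma), floor((n - 1) / 2))
  k <- stats::dnorm(seq(-half, half), sd = sigma)
  k <- k / sum(k)
  xx <- c(x[(n - half + 1):n], x, x[1:half])
  as.numeric(stats::filter(xx, k, sides = 2))[(half + 1):(half + n)]
}

# Centred moving average with window of `w` samples (forced odd);
# edges use the shrinking window.
moving_average <- function(x, w) {
  w <- max(1L, as.integer(w))
  if (w %% 2L == 0L) w <- w + 1L
  n <- length(x)
  half <- (w - 1L) %/% 2L
  vapply(seq_len(n), function(i) {
    lo <- max(1L, i - half)
    hi <- min(n, i + half)
    mean(x[lo:hi])
  }, numeric(1))
}

stopifnot_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    abort(sprintf("`%s` must be a single positive number.", name))
  }
  invisible(x)
}
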