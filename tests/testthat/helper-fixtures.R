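# Shared fixtures and independent oracles used across test files.

six_b <- c(0, 50, 100, 150, 600, 1000)

# Noise-free biexponential signal vector for one voxel.
clean_signal <- function(S0 = 1000, D = 0.9e-3, Dstar = 19e-3, f = 0.2,
                         b = six_b) {
  S0 * (f * exp(-b * Dstar) + (1 - f) * exp(-b * D))
}

# Independent OLS oracle for the high-b log-linear fit, via stats::lm.
ols_oracle <- function(signal, b = six_b, threshold = 100) {
  hi <- b > threshold
  fit <- stats::lm(log(signal[hi]) ~ b[hi])
  s0 <- signal[b == 0]
  list(d = -unname(coef(fit)[2]),
       f = (s0 - exp(unname(coef(fit)[1]))) / s0)
}

# Independent dense grid-search oracle for the 1-D D* refinement.
grid_dstar_oracle <- function(signal, b = six_b, d, f, S0 = signal[b == 0],
                              lower = 1e-3, upper = 200e-3, step = 1e-6) {
  grid <- seq(lower, upper, by = step)
  sse <- vapply(grid, function(ds) {
    pred <- S0 * (f * exp(-b * ds) + (1 - f) * exp(-b * d))
    sum((pred - signal)^2)
  }, numeric(1))
  grid[which.min(sse)]
}

# Analytic mean of the Rician distribution by numerical integration.
rician_mean_oracle <- function(nu, sigma) {
  # pdf exponent combined with the scaled Bessel factor to avoid overflow:
  # -(x^2 + nu^2)/(2 s^2) + x nu / s^2 = -(x - nu)^2 / (2 s^2)
  integrand <- function(x) {
    x^2 / sigma^2 * exp(-(x - nu)^2 / (2 * sigma^2)) *
      besselI(x * nu / sigma^2, 0, expon.scaled = TRUE)
  }
  stats::integrate(integrand, 0, nu + 20 * sigma, rel.tol = 1e-10)$value
}

# Small rectangular mask helper: n_per_slice voxels on each of n_slices.
block_mask <- function(n_per_slice, n_slices, voxel_dims = c(1, 1, 5)) {
  side <- ceiling(sqrt(n_per_slice))
  m <- array(FALSE, dim = c(side, side, n_slices))
  for (k in seq_len(n_slices)) {
    m[, , k][seq_len(n_per_slice)] <- TRUE
  }
  roi_mask(m, voxel_dims)
}
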