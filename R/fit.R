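#' Fitting configuration
#'
#' Settings for the voxelwise two-point ADC fit and the segmented
#' (stepwise) IVIM fit. The segmented fit assumes perfusion is negligible
#' above `perfusion_b_threshold` (D* >> D), estimates D and f there by
#' log-linear regression, and then refines D* alone by bounded
#' Levenberg-Marquardt with D, f and S0 held fixed.
#'
#' @param perfusion_b_threshold b-value (s/mm^2) above which the perfusion
#'   compartment is treated as fully attenuated. Default 100, so the
#'   six-b-value scheme uses b = 150, 600, 1000 for the D/f regression.
#' @param adc_b_pair The two b-values of the monoexponential ADC fit.
#' @param dstar_bounds Box bounds for D*, mm^2/s. The defaults bracket
#'   pseudo-diffusion values reported for abdominal tumors with wide margin.
#' @param dstar_init Start value for the D* refinement, mm^2/s.
#' @param f_floor Identifiability floor on f: below it the perfusion term
#'   is numerically invisible and D* is not estimated.
#' @param max_iterations,tol Levenberg-Marquardt iteration cap and
#'   convergence tolerance.
#' @return An object of class `"fit_config"`.
#' @export
fit_config <- function(perfusion_b_threshold = 100,
                       adc_b_pair = c(0, 1000),
                       dstar_bounds = c(1e-3, 200e-3),
                       dstar_init = 10e-3,
                       f_floor = 0.01,
                       max_iterations = 100,
                       tol = 1e-10) {
  stopifnot(length(adc_b_pair) == 2, adc_b_pair[1] < adc_b_pair[2],
            length(dstar_bounds) == 2, dstar_bounds[1] < dstar_bounds[2],
            dstar_init >= dstar_bounds[1], dstar_init <= dstar_bounds[2],
            f_floor >= 0, max_iterations >= 1, tol > 0)
  structure(
    list(perfusion_b_threshold = perfusion_b_threshold,
         adc_b_pair = adc_b_pair, dstar_bounds = dstar_bounds,
         dstar_init = dstar_init, f_floor = f_floor,
         max_iterations = max_iterations, tol = tol),
    class = "fit_config"
  )
}

#' Two-point ADC of one voxel
#'
#' Closed-form monoexponential fit through the signals at the two b-values
#' of `config$adc_b_pair` (default 0 and 1000 s/mm^2):
#' `ADC = -ln(S_b1 / S_b0) / (b1 - b0)`.
#'
#' @param signal Numeric vector of signals, one per b-value.
#' @param bvals b-value scheme matching `signal`.
#' @param config A [fit_config()].
#' @return A list: `adc` (mm^2/s, NA when a required signal is
#'   non-positive) and `flag` ([fit_flags()] bits).
#' @export
fit_adc_voxel <- function(signal, bvals, config = fit_config()) {
  bvals <- as.numeric(bvals)
  idx <- match(config$adc_b_pair, bvals)
  if (anyNA(idx)) {
    stop("ADC b-value pair not present in the scheme", call. = FALSE)
  }
  s <- signal[idx]
  if (any(!is.finite(s)) || any(s <= 0)) {
    return(list(adc = NA_real_, flag = fit_flags()[["excluded_nonpositive_signal"]]))
  }
  list(adc = -log(s[2] / s[1]) / diff(config$adc_b_pair), flag = 0L)
}

#' Segmented-fit D and f of one voxel
#'
#' Ordinary least squares of `ln(S_b)` against `b` restricted to
#' b-values above the perfusion threshold: the negated slope is the tissue
#' diffusivity D, and extrapolating the regression line to the y-axis gives
#' the perfusion-free intercept `S_int = exp(intercept)`, whose shortfall
#' against the measured b = 0 signal is the perfusion fraction
#' `f = (S_0 - S_int) / S_0`. f is clamped to \[0, 1\] and negative D to 0,
#' with flags.
#'
#' @inheritParams fit_adc_voxel
#' @return A list: `d`, `f`, `s_int` (extrapolated intercept amplitude),
#'   `flag`.
#' @export
fit_d_and_f <- function(signal, bvals, config = fit_config()) {
  bvals <- as.numeric(bvals)
  s0 <- signal[which(bvals == 0)[1]]
  hi <- which(bvals > config$perfusion_b_threshold & is.finite(signal) & signal > 0)
  if (length(hi) < 2 || !is.finite(s0) || s0 <= 0) {
    return(list(d = NA_real_, f = NA_real_, s_int = NA_real_,
                flag = fit_flags()[["excluded_nonpositive_signal"]]))
  }
  b <- bvals[hi]
  y <- log(signal[hi])
  slope <- stats::cov(b, y) / stats::var(b)
  intercept <- mean(y) - slope * mean(b)
  d <- -slope
  flag <- 0L
  if (d < 0) {
    d <- 0
    flag <- bitwOr(flag, fit_flags()[["clamped_d"]])
  }
  s_int <- exp(intercept)
  f <- (s0 - s_int) / s0
  if (f < 0 || f > 1) {
    f <- min(max(f, 0), 1)
    flag <- bitwOr(flag, fit_flags()[["clamped_f"]])
  }
  list(d = d, f = f, s_int = s_int, flag = flag)
}

#' D* refinement of one voxel
#'
#' One-dimensional bounded Levenberg-Marquardt least squares of the full
#' biexponential model over all b-values, with S0 fixed at the measured
#' b = 0 signal and D, f fixed at their segmented estimates; only D* is
#' free. Below the f identifiability floor D* is not estimated.
#'
#' @param signal,bvals,config As in [fit_adc_voxel()].
#' @param d,f Fixed values from [fit_d_and_f()].
#' @param S0 Fixed amplitude; defaults to the measured b = 0 signal.
#' @return A list: `dstar` (mm^2/s or NA) and `flag`.
#' @export
fit_dstar_voxel <- function(signal, bvals, d, f,
                            S0 = signal[which(as.numeric(bvals) == 0)[1]],
                            config = fit_config()) {
  bvals <- as.numeric(bvals)
  flags <- fit_flags()
  if (!is.finite(f) || f < config$f_floor) {
    return(list(dstar = NA_real_, flag = flags[["f_below_floor"]]))
  }
  lower <- max(d, config$dstar_bounds[1])
  upper <- config$dstar_bounds[2]
  resid_fun <- function(p) {
    S0 * (f * exp(-bvals * p[1]) + (1 - f) * exp(-bvals * d)) - signal
  }
  fit <- minpack.lm::nls.lm(
    par = c(dstar = min(max(config$dstar_init, lower), upper)),
    lower = lower, upper = upper, fn = resid_fun,
    control = minpack.lm::nls.lm.control(
      maxiter = config$max_iterations, ftol = config$tol, ptol = config$tol
    )
  )
  dstar <- unname(stats::coef(fit)[1])
  flag <- 0L
  edge <- 1e-8 * (upper - lower)
  if (dstar <= lower + edge || dstar >= upper - edge) {
    flag <- bitwOr(flag, flags[["dstar_at_bound"]])
  }
  list(dstar = dstar, flag = flag)
}

#' Full segmented IVIM + ADC fit of one voxel
#'
#' Convenience wrapper chaining [fit_adc_voxel()], [fit_d_and_f()] and
#' [fit_dstar_voxel()].
#'
#' @inheritParams fit_adc_voxel
#' @return One-row tibble: `adc`, `d`, `dstar`, `f`, `flag`.
#' @export
fit_ivim_voxel <- function(signal, bvals, config = fit_config()) {
  a <- fit_adc_voxel(signal, bvals, config)
  df <- fit_d_and_f(signal, bvals, config)
  flag <- bitwOr(a$flag, df$flag)
  if (is.na(df$f)) {
    ds <- list(dstar = NA_real_, flag = 0L)
  } else {
    ds <- fit_dstar_voxel(signal, bvals, d = df$d, f = df$f, config = config)
  }
  tibble::tibble(adc = a$adc, d = df$d, dstar = ds$dstar, f = df$f,
                 flag = bitwOr(flag, ds$flag))
}

#' Fit parameter maps over a masked volume
#'
#' Applies the two-point ADC fit and the segmented IVIM fit to every
#' in-mask voxel of a 4D series. The ADC and the D/f log-regression are
#' evaluated in closed form across all voxels at once; the D* refinement
#' runs voxel by voxel. Deterministic given its inputs; out-of-mask voxels
#' stay `NA`.
#'
#' @param dwi A [dwi_series()].
#' @param mask A [roi_mask()] with matching spatial dimensions.
#' @param config A [fit_config()].
#' @return A [parameter_maps()] object.
#' @export
fit_volume <- function(dwi, mask, config = fit_config()) {
  stopifnot(inherits(dwi, "dwi_series"), inherits(mask, "roi_mask"))
  dims <- dim(dwi$signal)[1:3]
  if (!identical(dim(mask$mask), dims)) {
    stop("mask dimensions do not match the DWI spatial dimensions", call. = FALSE)
  }
  bvals <- dwi$bvals
  flags <- fit_flags()
  empty <- array(NA_real_, dim = dims)
  maps <- parameter_maps(adc = empty, d = empty, dstar = empty, f = empty,
                         flags = array(NA_integer_, dim = dims),
                         voxel_dims = dwi$voxel_dims)
  idx <- which(mask$mask)
  n <- length(idx)
  if (n == 0) return(maps)

  # n x nb signal matrix of in-mask voxels
  nb <- length(bvals)
  sig <- matrix(0, n, nb)
  for (bi in seq_len(nb)) {
    vol <- dwi$signal[, , , bi]
    sig[, bi] <- vol[idx]
  }

  # vectorized two-point ADC
  pair_idx <- match(config$adc_b_pair, bvals)
  if (anyNA(pair_idx)) stop("ADC b-value pair not present in the scheme", call. = FALSE)
  s0p <- sig[, pair_idx[1]]
  s1p <- sig[, pair_idx[2]]
  adc_ok <- is.finite(s0p) & is.finite(s1p) & s0p > 0 & s1p > 0
  adc <- ifelse(adc_ok, -log(s1p / s0p) / diff(config$adc_b_pair), NA_real_)
  flag <- ifelse(adc_ok, 0L, flags[["excluded_nonpositive_signal"]])

  # vectorized high-b log-regression for D and f
  hi <- which(bvals > config$perfusion_b_threshold)
  s0 <- sig[, which(bvals == 0)[1]]
  hi_ok <- rowSums(is.finite(sig[, hi, drop = FALSE]) &
                     sig[, hi, drop = FALSE] > 0) == length(hi) &
    is.finite(s0) & s0 > 0
  b <- bvals[hi]
  y <- log(pmax(sig[, hi, drop = FALSE], .Machine$double.xmin))
  bc <- b - mean(b)
  slope <- as.vector(y %*% bc) / sum(bc^2)
  intercept <- rowMeans(y) - slope * mean(b)
  d <- -slope
  clamp_d <- hi_ok & d < 0
  d[clamp_d] <- 0
  s_int <- exp(intercept)
  f <- (s0 - s_int) / s0
  clamp_f <- hi_ok & (f < 0 | f > 1)
  f <- pmin(pmax(f, 0), 1)
  d[!hi_ok] <- NA_real_
  f[!hi_ok] <- NA_real_
  flag <- bitwOr(flag, ifelse(hi_ok, 0L, flags[["excluded_nonpositive_signal"]]))
  flag <- bitwOr(flag, ifelse(clamp_d, flags[["clamped_d"]], 0L))
  flag <- bitwOr(flag, ifelse(clamp_f, flags[["clamped_f"]], 0L))

  # voxelwise bounded D* refinement
  dstar <- rep(NA_real_, n)
  for (v in seq_len(n)) {
    if (!hi_ok[v]) next
    ds <- fit_dstar_voxel(sig[v, ], bvals, d = d[v], f = f[v], S0 = s0[v],
                          config = config)
    dstar[v] <- ds$dstar
    flag[v] <- bitwOr(flag[v], ds$flag)
  }

  maps$adc[idx] <- adc
  maps$d[idx] <- d
  maps$dstar[idx] <- dstar
  maps$f[idx] <- f
  maps$flags[idx] <- as.integer(flag)
  maps
}
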