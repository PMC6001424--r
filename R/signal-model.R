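#' Diffusion-weighting scheme
#'
#' Validates and returns a b-value scheme for a multi-b-value DWI acquisition.
#' A scheme usable for segmented IVIM fitting must contain b = 0, be strictly
#' increasing and non-negative, and hold at least two b-values above the
#' perfusion threshold so the high-b log-linear regression is determined.
#'
#' @param values Numeric vector of b-values in s/mm^2.
#' @param perfusion_b_threshold b-value (s/mm^2) above which perfusion is
#'   treated as negligible; used only to check the scheme supports a
#'   segmented fit. Default 100.
#' @return The validated numeric vector, classed `"bvalue_scheme"`.
#' @examples
#' bvalue_scheme(c(0, 50, 100, 150, 600, 1000))
#' @export
bvalue_scheme <- function(values, perfusion_b_threshold = 100) {
  values <- as.numeric(values)
  if (anyNA(values) || any(values < 0)) {
    stop("b-values must be non-negative and non-missing", call. = FALSE)
  }
  if (is.unsorted(values, strictly = TRUE)) {
    stop("b-values must be strictly increasing", call. = FALSE)
  }
  if (values[1] != 0) {
    stop("b-value scheme must contain b = 0", call. = FALSE)
  }
  if (length(values) < 3 || sum(values > perfusion_b_threshold) < 2) {
    stop("scheme needs b = 0 plus at least two b-values above the perfusion threshold (",
         perfusion_b_threshold, " s/mm^2)", call. = FALSE)
  }
  structure(values, class = "bvalue_scheme")
}

#' Default six-b-value acquisition scheme
#'
#' The acquisition emulated throughout the package:
#' b = 0, 50, 100, 150, 600, 1000 s/mm^2.
#'
#' @return A [bvalue_scheme()].
#' @export
default_bvals <- function() {
  bvalue_scheme(c(0, 50, 100, 150, 600, 1000))
}

#' IVIM parameter set for one voxel
#'
#' Bundles the four parameters of the biexponential IVIM signal model and
#' checks their physical constraints: positive b = 0 amplitude, non-negative
#' tissue diffusivity `D`, pseudo-diffusivity `Dstar >= D`, and perfusion
#' fraction `f` in \[0, 1\]. Diffusivities are in mm^2/s throughout the
#' computational layer; the reporting layer rescales to the conventional
#' 1e-6 mm^2/s display unit (and f to percent) only at I/O.
#'
#' @param S0 Signal amplitude at b = 0 (arbitrary units), > 0.
#' @param D Slow (tissue) diffusion coefficient, mm^2/s, >= 0.
#' @param Dstar Fast (pseudo-)diffusion coefficient, mm^2/s, >= D. May be NA
#'   when `f = 0` (the perfusion compartment is absent).
#' @param f Perfusion fraction in \[0, 1\].
#' @return A list with class `"ivim_params"`.
#' @examples
#' ivim_params(S0 = 1000, D = 0.9e-3, Dstar = 19e-3, f = 0.2)
#' @export
ivim_params <- function(S0, D, Dstar = NA_real_, f = 0) {
  stopifnot(length(S0) == 1, length(D) == 1, length(Dstar) == 1, length(f) == 1)
  if (!is.finite(S0) || S0 <= 0) stop("S0 must be positive", call. = FALSE)
  if (!is.finite(D) || D < 0) stop("D must be non-negative", call. = FALSE)
  if (!is.finite(f) || f < 0 || f > 1) {
    stop("f must lie in [0, 1]", call. = FALSE)
  }
  if (f > 0) {
    if (!is.finite(Dstar)) stop("Dstar is required when f > 0", call. = FALSE)
    if (Dstar < D) stop("Dstar must be >= D", call. = FALSE)
  }
  structure(list(S0 = S0, D = D, Dstar = Dstar, f = f), class = "ivim_params")
}

#' @export
print.ivim_params <- function(x, ...) {
  cat(sprintf(
    "IVIM parameters: S0 = %.4g, D = %.4g mm^2/s, D* = %.4g mm^2/s, f = %.3f\n",
    x$S0, x$D, x$Dstar, x$f
  ))
  invisible(x)
}

#' Biexponential IVIM signal
#'
#' Forward model of the diffusion-weighted signal as the sum of a perfusing
#' (pseudo-diffusion) and a tissue compartment:
#' \deqn{S(b) = S_0 [ f e^{-b D^*} + (1 - f) e^{-b D} ]}
#'
#' @param params An [ivim_params()] object.
#' @param b Numeric vector of b-values, s/mm^2, >= 0.
#' @return Signal amplitudes, same length as `b`; non-increasing in `b`.
#' @examples
#' p <- ivim_params(S0 = 1000, D = 1e-3, Dstar = 20e-3, f = 0.2)
#' ivim_signal(p, c(0, 1000))
#' @export
ivim_signal <- function(params, b) {
  if (!inherits(params, "ivim_params")) params <- do.call(ivim_params, params)
  if (any(b < 0)) stop("b must be non-negative", call. = FALSE)
  dstar <- if (params$f > 0) params$Dstar else params$D
  params$S0 * (params$f * exp(-b * dstar) + (1 - params$f) * exp(-b * params$D))
}

#' Monoexponential (ADC) signal
#'
#' \deqn{S(b) = S_0 e^{-b \cdot ADC}}
#'
#' @param S0 Signal amplitude at b = 0, > 0.
#' @param adc Apparent diffusion coefficient, mm^2/s.
#' @param b Numeric vector of b-values, s/mm^2, >= 0.
#' @return Signal amplitudes, same length as `b`.
#' @examples
#' mono_signal(1000, 1e-3, 1000)
#' @export
mono_signal <- function(S0, adc, b) {
  stopifnot(S0 > 0, all(b >= 0))
  S0 * exp(-b * adc)
}

# Vectorized forward model over a table of voxel parameters: returns an
# n_voxel x n_b matrix. Rows with f = 0 ignore Dstar entirely.
ivim_signal_matrix <- function(S0, D, Dstar, f, bvals) {
  n <- length(D)
  b <- matrix(bvals, nrow = n, ncol = length(bvals), byrow = TRUE)
  dstar <- ifelse(f > 0, Dstar, D)
  S0 * (f * exp(-b * dstar) + (1 - f) * exp(-b * D))
}
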