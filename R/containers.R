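#' 4D diffusion-weighted series
#'
#' Couples a 4D magnitude-signal array (x, y, z, b-index) with its b-value
#' scheme and voxel dimensions. The fourth dimension must match the number
#' of b-values and signals must be non-negative (magnitude data).
#'
#' @param signal 4D numeric array, arbitrary units.
#' @param bvals A [bvalue_scheme()] or numeric vector of b-values, s/mm^2.
#' @param voxel_dims Numeric length-3, voxel edge lengths in mm.
#' @return An object of class `"dwi_series"`.
#' @export
dwi_series <- function(signal, bvals, voxel_dims = c(1, 1, 5)) {
  if (length(dim(signal)) != 4) stop("signal must be a 4D array", call. = FALSE)
  bvals <- if (inherits(bvals, "bvalue_scheme")) bvals else bvalue_scheme(bvals)
  if (dim(signal)[4] != length(bvals)) {
    stop(sprintf("4th dimension (%d volumes) does not match b-value count (%d)",
                 dim(signal)[4], length(bvals)), call. = FALSE)
  }
  if (any(signal < 0, na.rm = TRUE)) {
    stop("magnitude signals must be non-negative", call. = FALSE)
  }
  stopifnot(length(voxel_dims) == 3, all(voxel_dims > 0))
  structure(
    list(signal = signal, bvals = as.numeric(bvals),
         voxel_dims = as.numeric(voxel_dims)),
    class = "dwi_series"
  )
}

#' @export
print.dwi_series <- function(x, ...) {
  d <- dim(x$signal)
  cat(sprintf("DWI series: %d x %d x %d voxels, %d b-values (%s s/mm^2)\n",
              d[1], d[2], d[3], d[4], paste(x$bvals, collapse = ", ")))
  cat(sprintf("voxel size: %s mm\n", paste(x$voxel_dims, collapse = " x ")))
  invisible(x)
}

#' Region-of-interest mask
#'
#' A 3D logical mask with its voxel dimensions, marking the whole-lesion
#' region over all slices.
#'
#' @param mask 3D logical (or 0/1) array.
#' @param voxel_dims Numeric length-3, mm per axis.
#' @return An object of class `"roi_mask"`.
#' @export
roi_mask <- function(mask, voxel_dims = c(1, 1, 5)) {
  if (length(dim(mask)) != 3) stop("mask must be a 3D array", call. = FALSE)
  storage.mode(mask) <- "logical"
  if (anyNA(mask)) stop("mask must not contain NA", call. = FALSE)
  stopifnot(length(voxel_dims) == 3, all(voxel_dims > 0))
  structure(list(mask = mask, voxel_dims = as.numeric(voxel_dims)),
            class = "roi_mask")
}

#' @export
print.roi_mask <- function(x, ...) {
  cat(sprintf("ROI mask: %s grid, %d in-mask voxels\n",
              paste(dim(x$mask), collapse = " x "), sum(x$mask)))
  invisible(x)
}

#' Voxel fit-status flags
#'
#' Bit flags recorded per voxel during map fitting. `ok` (0) means a clean
#' fit; other conditions OR together: `clamped_f` — the extrapolated
#' perfusion fraction fell outside \[0, 1\] and was clamped; `clamped_d` — a
#' negative high-b slope was clamped to D = 0; `dstar_at_bound` — the D*
#' optimum hit a box bound; `excluded_nonpositive_signal` — a required
#' signal was <= 0 so the voxel has no value; `f_below_floor` — f was below
#' the identifiability floor so D* was not estimated.
#'
#' @return Named integer vector of flag bits.
#' @export
fit_flags <- function() {
  c(ok = 0L, clamped_f = 1L, clamped_d = 2L, dstar_at_bound = 4L,
    excluded_nonpositive_signal = 8L, f_below_floor = 16L)
}

#' Co-registered IVIM/ADC parameter maps
#'
#' Holds 3D maps of ADC, D, D* (mm^2/s) and f (fraction) plus an integer
#' flag map (see [fit_flags()]). Out-of-mask voxels are `NA` in every map
#' and carry flag `NA`.
#'
#' @param adc,d,dstar,f 3D numeric arrays of identical dimension.
#' @param flags 3D integer array of OR-ed [fit_flags()] bits.
#' @param voxel_dims Numeric length-3, mm per axis.
#' @return An object of class `"parameter_maps"`.
#' @export
parameter_maps <- function(adc, d, dstar, f, flags, voxel_dims = c(1, 1, 5)) {
  dims <- dim(adc)
  if (length(dims) != 3) stop("maps must be 3D arrays", call. = FALSE)
  for (m in list(d, dstar, f, flags)) {
    if (!identical(dim(m), dims)) stop("all maps must share dimensions", call. = FALSE)
  }
  storage.mode(flags) <- "integer"
  structure(
    list(adc = adc, d = d, dstar = dstar, f = f, flags = flags,
         voxel_dims = as.numeric(voxel_dims)),
    class = "parameter_maps"
  )
}

#' @export
print.parameter_maps <- function(x, ...) {
  n <- sum(!is.na(x$flags))
  cat(sprintf("IVIM parameter maps: %s grid, %d fitted voxels\n",
              paste(dim(x$adc), collapse = " x "), n))
  invisible(x)
}

#' @rdname parameter_maps
#' @param x A `"parameter_maps"` object.
#' @param ... Unused.
#' @return `as_tibble()`: one row per fitted voxel with coordinates, the four
#'   parameter values (internal units) and the flag bits.
#' @export
as_tibble.parameter_maps <- function(x, ...) {
  idx <- which(!is.na(x$flags), arr.ind = TRUE)
  tibble::tibble(
    i = idx[, 1], j = idx[, 2], k = idx[, 3],
    adc = x$adc[idx], d = x$d[idx], dstar = x$dstar[idx], f = x$f[idx],
    flag = x$flags[idx]
  )
}
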