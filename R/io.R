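#' Read and write FSL-style b-value files
#'
#' A `.bval` file is a single line of whitespace-separated b-values, one
#' per diffusion volume.
#'
#' @param path File path.
#' @return `read_bvals()`: a [bvalue_scheme()].
#' @export
read_bvals <- function(path) {
  if (!file.exists(path)) stop("bval file not found: ", path, call. = FALSE)
  vals <- scan(path, what = numeric(), quiet = TRUE)
  bvalue_scheme(vals)
}

#' @rdname read_bvals
#' @param bvals A [bvalue_scheme()] or numeric vector.
#' @export
write_bvals <- function(bvals, path) {
  writeLines(paste(as.numeric(bvals), collapse = " "), path)
  invisible(path)
}

#' Read a 4D DWI acquisition
#'
#' Loads a 4D NIfTI volume and its b-value file into a [dwi_series()],
#' preserving the header voxel dimensions. The number of volumes must
#' match the number of b-values.
#'
#' @param path_image Path to a 4D NIfTI (.nii or .nii.gz).
#' @param path_bvals Path to the matching .bval file.
#' @return A [dwi_series()].
#' @export
read_dwi <- function(path_image, path_bvals) {
  if (!file.exists(path_image)) {
    stop("DWI image not found: ", path_image, call. = FALSE)
  }
  img <- RNifti::readNifti(path_image)
  if (length(dim(img)) != 4) {
    stop("expected a 4D NIfTI image, got ", length(dim(img)), "D", call. = FALSE)
  }
  bvals <- read_bvals(path_bvals)
  if (dim(img)[4] != length(bvals)) {
    stop(sprintf("image has %d volumes but bval file lists %d b-values",
                 dim(img)[4], length(bvals)), call. = FALSE)
  }
  vd <- RNifti::pixdim(img)[1:3]
  dwi_series(array(as.numeric(img), dim = dim(img)), bvals, vd)
}

#' @rdname read_dwi
#' @param dwi A [dwi_series()] to write (`path_bvals` may be `NULL` to
#'   skip the scheme).
#' @export
write_dwi <- function(dwi, path_image, path_bvals = NULL) {
  stopifnot(inherits(dwi, "dwi_series"))
  img <- RNifti::asNifti(dwi$signal)
  RNifti::pixdim(img) <- c(dwi$voxel_dims, 1)
  RNifti::writeNifti(img, path_image)
  if (!is.null(path_bvals)) write_bvals(dwi$bvals, path_bvals)
  invisible(path_image)
}

#' Read and write ROI masks as NIfTI
#'
#' Masks are stored as 3D uint8 volumes (1 in-mask, 0 background).
#'
#' @param path File path (.nii or .nii.gz).
#' @return `read_mask()`: a [roi_mask()].
#' @export
read_mask <- function(path) {
  if (!file.exists(path)) stop("mask image not found: ", path, call. = FALSE)
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 3) stop("expected a 3D mask image", call. = FALSE)
  roi_mask(array(as.numeric(img) != 0, dim = dim(img)),
           RNifti::pixdim(img)[1:3])
}

#' @rdname read_mask
#' @param mask A [roi_mask()].
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "roi_mask"))
  img <- RNifti::asNifti(array(as.integer(mask$mask), dim = dim(mask$mask)))
  RNifti::pixdim(img) <- mask$voxel_dims
  RNifti::writeNifti(img, path, datatype = "uint8")
  invisible(path)
}

#' Write and read parameter-map sets
#'
#' `write_maps()` writes one NIfTI per map (`adc`, `d`, `dstar`, `f`,
#' `flags`) plus a JSON sidecar recording the storage units (diffusivities
#' in mm^2/s, f as a fraction), the display scale used in reports
#' (1e-6 mm^2/s; percent), the flag encoding and a content hash of the
#' fitting configuration when one is supplied. Flags are stored as
#' integer codes.
#'
#' @param maps A [parameter_maps()] object.
#' @param out_dir Output directory (created if needed).
#' @param config Optional [fit_config()] recorded in the sidecar.
#' @param prefix File-name prefix.
#' @return Invisibly, the named vector of file paths.
#' @export
write_maps <- function(maps, out_dir, config = NULL, prefix = "ivim") {
  stopifnot(inherits(maps, "parameter_maps"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c()
  for (nm in c("adc", "d", "dstar", "f")) {
    p <- file.path(out_dir, sprintf("%s_%s.nii.gz", prefix, nm))
    img <- RNifti::asNifti(maps[[nm]])
    RNifti::pixdim(img) <- maps$voxel_dims
    RNifti::writeNifti(img, p, datatype = "double")
    paths[nm] <- p
  }
  fl <- maps$flags
  fl[is.na(fl)] <- -1L
  p <- file.path(out_dir, sprintf("%s_flags.nii.gz", prefix))
  img <- RNifti::asNifti(fl)
  RNifti::pixdim(img) <- maps$voxel_dims
  RNifti::writeNifti(img, p, datatype = "int16")
  paths["flags"] <- p
  sidecar <- list(
    storage_units = list(adc = "mm^2/s", d = "mm^2/s", dstar = "mm^2/s",
                         f = "fraction"),
    display_scale = list(diffusivity = "1e-6 mm^2/s", f = "percent"),
    flag_bits = as.list(fit_flags()),
    out_of_mask_flag = -1L,
    config_hash = if (is.null(config)) NULL else rlang::hash(unclass(config))
  )
  sp <- file.path(out_dir, sprintf("%s_maps.json", prefix))
  jsonlite::write_json(sidecar, sp, auto_unbox = TRUE, pretty = TRUE,
                       null = "null")
  paths["sidecar"] <- sp
  invisible(paths)
}

#' @rdname write_maps
#' @export
read_maps <- function(out_dir, prefix = "ivim") {
  rd <- function(nm) {
    img <- RNifti::readNifti(file.path(out_dir, sprintf("%s_%s.nii.gz", prefix, nm)))
    list(arr = array(as.numeric(img), dim = dim(img)),
         vd = RNifti::pixdim(img)[1:3])
  }
  adc <- rd("adc"); d <- rd("d"); dstar <- rd("dstar"); f <- rd("f")
  fl <- rd("flags")
  flags <- array(as.integer(fl$arr), dim = dim(fl$arr))
  flags[flags == -1L] <- NA_integer_
  parameter_maps(adc$arr, d$arr, dstar$arr, f$arr, flags, adc$vd)
}

#' Pipeline configuration
#'
#' Bundles every setting of the end-to-end pipeline: the fit
#' configuration, histogram bin widths, statistics settings, the synthetic
#' cohort description, the global seed and the output directory. The
#' object round-trips losslessly through JSON via [write_config()] /
#' [read_config()]; unknown keys in a config file are rejected.
#'
#' @param groups Named integer vector: group label -> cases to simulate.
#' @param snr Signal-to-noise ratio at b = 0 for simulated cases.
#' @param axes Lesion ellipsoid semi-axes in voxels.
#' @param voxel_dims Voxel dimensions, mm.
#' @param bvals b-value scheme.
#' @param fit A [fit_config()].
#' @param bin_widths Entropy/display bin widths per parameter
#'   (display units).
#' @param alpha Significance level.
#' @param f_band Perfusion-fraction band (percent) for the voxelwise
#'   correlation analysis.
#' @param positive,negative Group labels used for the ROC contrast.
#' @param seed Integer seed governing all randomness.
#' @param out_dir Output directory.
#' @return An object of class `"pipeline_config"`.
#' @export
pipeline_config <- function(groups = c(NB = 4, W = 4),
                            snr = 50,
                            axes = c(10, 10, 4),
                            voxel_dims = c(1, 1, 5),
                            bvals = default_bvals(),
                            fit = fit_config(),
                            bin_widths = default_bin_width(),
                            alpha = 0.05,
                            f_band = c(25, 40),
                            positive = "NB", negative = "W",
                            seed = 1L,
                            out_dir = tempfile("ivim_run_")) {
  stopifnot(length(groups) >= 2, all(groups >= 1), alpha > 0, alpha < 1)
  structure(
    list(groups = groups, snr = snr, axes = axes, voxel_dims = voxel_dims,
         bvals = as.numeric(bvals), fit = fit, bin_widths = bin_widths,
         alpha = alpha, f_band = f_band, positive = positive,
         negative = negative, seed = as.integer(seed), out_dir = out_dir),
    class = "pipeline_config"
  )
}

#' @rdname pipeline_config
#' @param config A `"pipeline_config"`.
#' @param path JSON file path.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  x <- unclass(config)
  x$fit <- unclass(x$fit)
  x$groups <- as.list(x$groups)
  x$bin_widths <- as.list(x$bin_widths)
  jsonlite::write_json(x, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  proto <- pipeline_config()
  unknown <- setdiff(names(x), names(unclass(proto)))
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  fit_args <- x$fit
  unknown_fit <- setdiff(names(fit_args), names(unclass(fit_config())))
  if (length(unknown_fit)) {
    stop("unknown fit config key(s): ", paste(unknown_fit, collapse = ", "),
         call. = FALSE)
  }
  pipeline_config(
    groups = unlist(x$groups), snr = x$snr, axes = x$axes,
    voxel_dims = x$voxel_dims, bvals = x$bvals,
    fit = do.call(fit_config, fit_args),
    bin_widths = unlist(x$bin_widths), alpha = x$alpha, f_band = x$f_band,
    positive = x$positive, negative = x$negative, seed = x$seed,
    out_dir = x$out_dir
  )
}
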