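# Evaluate expr under a temporary RNG seed, restoring the caller's stream.
# seed = NULL means "use the ambient RNG state" (for nested generators that
# must share one stream).
with_local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  expr
}

#' Specification of one synthetic lesion
#'
#' Describes an ellipsoidal lesion whose voxelwise IVIM parameters are drawn
#' from per-parameter sampling distributions, imaged at a given signal-to-
#' noise ratio. The distribution families default to normal for `D` and `f`
#' and log-normal for `Dstar` (pseudo-diffusion values are strictly positive
#' and right-skewed); `location` and `scale` are always the distribution's
#' mean and standard deviation on the natural (moment) scale, in internal
#' units (mm^2/s; f as a fraction).
#'
#' @param axes Ellipsoid semi-axes in voxels, length 3, each >= 2.
#' @param voxel_dims Voxel edge lengths in mm, length 3.
#' @param d,dstar,f Lists `list(location =, scale =)` for the voxelwise
#'   sampling distribution of each parameter.
#' @param families Named character vector of distribution families
#'   (`"normal"` or `"lognormal"`) for `d`, `dstar`, `f`.
#' @param S0 Noise-free signal amplitude at b = 0, arbitrary units.
#' @param snr Signal-to-noise ratio at b = 0, defined as `S0 / sigma` of the
#'   Rician noise; `Inf` gives noiseless data.
#' @param smooth_amplitude Optional relative amplitude (>= 0) of a smooth
#'   intra-lesion modulation field applied to the `d` and `f` locations,
#'   emulating coherent spatial heterogeneity. 0 disables it.
#' @return An object of class `"lesion_spec"`.
#' @examples
#' lesion_spec(f = list(location = 0.2, scale = 0.05))
#' @export
lesion_spec <- function(axes = c(10, 10, 4),
                        voxel_dims = c(1, 1, 5),
                        d = list(location = 0.9e-3, scale = 0.25e-3),
                        dstar = list(location = 19e-3, scale = 10e-3),
                        f = list(location = 0.2, scale = 0.1),
                        families = c(d = "normal", dstar = "lognormal", f = "normal"),
                        S0 = 1000,
                        snr = 50,
                        smooth_amplitude = 0) {
  stopifnot(length(axes) == 3, length(voxel_dims) == 3, all(voxel_dims > 0))
  if (any(axes < 2)) stop("ellipsoid semi-axes must be >= 2 voxels", call. = FALSE)
  for (p in list(d = d, dstar = dstar, f = f)) {
    if (!is.finite(p$scale) || p$scale < 0) {
      stop("distribution scale must be a non-negative number", call. = FALSE)
    }
  }
  if (d$location < 0 || dstar$location < d$location ||
      f$location < 0 || f$location > 1) {
    stop("distribution locations must satisfy the IVIM parameter constraints",
         call. = FALSE)
  }
  if (!all(c("d", "dstar", "f") %in% names(families)) ||
      !all(families %in% c("normal", "lognormal"))) {
    stop("families must name d, dstar and f as \"normal\" or \"lognormal\"",
         call. = FALSE)
  }
  stopifnot(S0 > 0, snr > 0, smooth_amplitude >= 0)
  structure(
    list(axes = axes, voxel_dims = voxel_dims, d = d, dstar = dstar, f = f,
         families = families, S0 = S0, snr = snr,
         smooth_amplitude = smooth_amplitude),
    class = "lesion_spec"
  )
}

# Draw n values from one voxel-parameter distribution with redraw truncation
# to [lower, upper]; moment-matched log-normal when family == "lognormal".
sample_trunc <- function(n, location, scale, family, lower = 0, upper = Inf) {
  if (scale == 0) return(rep(location, n))
  draw <- function(m) {
    if (family == "lognormal") {
      sdlog <- sqrt(log1p((scale / location)^2))
      meanlog <- log(location) - sdlog^2 / 2
      stats::rlnorm(m, meanlog, sdlog)
    } else {
      stats::rnorm(m, location, scale)
    }
  }
  x <- draw(n)
  bad <- which(x < lower | x > upper)
  guard <- 0
  while (length(bad) > 0 && guard < 100) {
    x[bad] <- draw(length(bad))
    bad <- which(x < lower | x > upper)
    guard <- guard + 1
  }
  if (length(bad) > 0) x[bad] <- pmin(pmax(x[bad], lower), upper)
  x
}

#' Sample voxelwise IVIM parameters
#'
#' Draws `n` voxel parameter sets from a lesion's sampling distributions.
#' `D` and `Dstar` are redrawn into their valid domains (D >= 0, then
#' Dstar >= D voxel by voxel) so no probability mass piles up at the bounds;
#' `f` is clipped to \[0, 1\], the only hard physical interval.
#'
#' @param spec A [lesion_spec()].
#' @param n Number of voxels, >= 1.
#' @param seed Optional integer seed (NULL uses the current RNG stream).
#' @return A tibble with columns `S0`, `D`, `Dstar`, `f`, one row per voxel.
#' @export
sample_voxel_params <- function(spec, n, seed = NULL) {
  stopifnot(inherits(spec, "lesion_spec"), n >= 1)
  with_local_seed(seed, {
    d <- sample_trunc(n, spec$d$location, spec$d$scale, spec$families[["d"]],
                      lower = 0)
    dstar <- sample_trunc(n, spec$dstar$location, spec$dstar$scale,
                          spec$families[["dstar"]], lower = 0)
    # enforce Dstar >= D per voxel by redrawing the offending Dstar values
    bad <- which(dstar < d)
    guard <- 0
    while (length(bad) > 0 && guard < 100) {
      dstar[bad] <- sample_trunc(length(bad), spec$dstar$location,
                                 spec$dstar$scale, spec$families[["dstar"]],
                                 lower = 0)
      bad <- bad[dstar[bad] < d[bad]]
      guard <- guard + 1
    }
    if (length(bad) > 0) dstar[bad] <- d[bad]
    f <- sample_trunc(n, spec$f$location, spec$f$scale, spec$families[["f"]],
                      lower = -Inf, upper = Inf)
    f <- pmin(pmax(f, 0), 1)
    tibble::tibble(S0 = spec$S0, D = d, Dstar = dstar, f = f)
  })
}

#' Add Rician magnitude noise
#'
#' Magnitude-MRI noise model: independent zero-mean Gaussian noise of scale
#' `sigma` corrupts the real and imaginary channels, and the magnitude
#' `sqrt((signal + g1)^2 + g2^2)` is observed. Zero `sigma` returns the
#' signal unchanged. The output is always non-negative; for zero underlying
#' signal the result is Rayleigh with mean `sigma * sqrt(pi/2)`.
#'
#' @param signal Numeric vector of noise-free amplitudes, >= 0.
#' @param sigma Noise scale, >= 0.
#' @param seed Optional integer seed.
#' @return Noisy magnitudes, same length as `signal`.
#' @export
add_rician_noise <- function(signal, sigma, seed = NULL) {
  stopifnot(sigma >= 0)
  if (sigma == 0) return(signal)
  with_local_seed(seed, {
    n <- length(signal)
    sqrt((signal + stats::rnorm(n, 0, sigma))^2 + stats::rnorm(n, 0, sigma)^2)
  })
}

# Smooth 3D modulation field in [-1, 1]: a random low-frequency cosine mix.
smooth_field <- function(dims) {
  ax <- lapply(dims, function(d) (seq_len(d) - 0.5) / d)
  g <- expand.grid(x = ax[[1]], y = ax[[2]], z = ax[[3]])
  field <- 0
  for (h in 1:3) {
    ph <- stats::runif(3, 0, 2 * pi)
    w <- stats::rnorm(1)
    field <- field + w * cos(2 * pi * h * g$x + ph[1]) *
      cos(2 * pi * h * g$y + ph[2]) * cos(2 * pi * h * g$z + ph[3])
  }
  field <- array(field, dim = dims)
  m <- max(abs(field))
  if (m > 0) field / m else field
}

#' Generate a synthetic DWI phantom
#'
#' Builds an ellipsoidal lesion on a background-padded grid, samples
#' voxelwise IVIM parameters from the lesion spec, evaluates the
#' biexponential forward model at every b-value, and corrupts all voxels
#' (lesion and background) with Rician magnitude noise of scale
#' `sigma = S0 / snr`. Background voxels have zero underlying signal, i.e.
#' they sit at the Rayleigh noise floor.
#'
#' @param spec A [lesion_spec()].
#' @param bvals A [bvalue_scheme()]; defaults to the six-b-value scheme.
#' @param seed Optional integer seed.
#' @param margin Background voxels padded around the ellipsoid per side.
#' @return A list of class `"dwi_phantom"`: `dwi` (a [dwi_series()]),
#'   `mask` (a [roi_mask()]), and `truth` (a [parameter_maps()] holding the
#'   ground-truth D, D*, f and the implied two-point ADC of the noiseless
#'   signal).
#' @export
generate_phantom <- function(spec, bvals = default_bvals(), seed = NULL,
                             margin = 2) {
  stopifnot(inherits(spec, "lesion_spec"))
  bvals <- if (inherits(bvals, "bvalue_scheme")) bvals else bvalue_scheme(bvals)
  with_local_seed(seed, {
    dims <- ceiling(2 * spec$axes) + 2 * margin
    centre <- (dims + 1) / 2
    g <- expand.grid(i = seq_len(dims[1]), j = seq_len(dims[2]),
                     k = seq_len(dims[3]))
    inside <- ((g$i - centre[1]) / spec$axes[1])^2 +
      ((g$j - centre[2]) / spec$axes[2])^2 +
      ((g$k - centre[3]) / spec$axes[3])^2 <= 1
    mask <- array(inside, dim = dims)
    n_in <- sum(mask)

    params <- sample_voxel_params(spec, n_in)
    if (spec$smooth_amplitude > 0) {
      fld <- smooth_field(dims)[mask]
      params$D <- pmax(params$D * (1 + spec$smooth_amplitude * fld), 0)
      params$f <- pmin(pmax(params$f * (1 + spec$smooth_amplitude * fld), 0), 1)
    }

    clean <- ivim_signal_matrix(params$S0, params$D, params$Dstar, params$f,
                                as.numeric(bvals))
    nb <- length(bvals)
    signal <- array(0, dim = c(dims, nb))
    for (bi in seq_len(nb)) {
      vol <- array(0, dim = dims)
      vol[mask] <- clean[, bi]
      signal[, , , bi] <- vol
    }
    sigma <- if (is.infinite(spec$snr)) 0 else spec$S0 / spec$snr
    if (sigma > 0) {
      signal <- array(add_rician_noise(as.vector(signal), sigma),
                      dim = dim(signal))
    }

    to_map <- function(v) {
      m <- array(NA_real_, dim = dims)
      m[mask] <- v
      m
    }
    b_pair <- range(as.numeric(bvals))
    s_hi <- ivim_signal_matrix(params$S0, params$D, params$Dstar, params$f,
                               b_pair[2])[, 1]
    truth <- parameter_maps(
      adc = to_map(-log(s_hi / params$S0) / b_pair[2]),
      d = to_map(params$D),
      dstar = to_map(ifelse(params$f > 0, params$Dstar, NA_real_)),
      f = to_map(params$f),
      flags = {
        fl <- array(NA_integer_, dim = dims)
        fl[mask] <- 0L
        fl
      },
      voxel_dims = spec$voxel_dims
    )
    structure(
      list(dwi = dwi_series(signal, bvals, spec$voxel_dims),
           mask = roi_mask(mask, spec$voxel_dims),
           truth = truth),
      class = "dwi_phantom"
    )
  })
}

#' Lesion-size eligibility check
#'
#' A lesion enters the analysis only if it is large enough to support
#' whole-tumor histogram statistics: the largest single-slice in-mask area
#' must reach 3 cm^2 and the total in-mask volume 6 cm^3 (both thresholds
#' inclusive; smaller lesions are excluded). Areas and volumes are voxel
#' counts times the voxel dimensions; slices are taken along the third
#' (slice) axis.
#'
#' @param mask A [roi_mask()].
#' @param area_min_cm2,volume_min_cm3 Eligibility thresholds.
#' @return A one-row tibble: `eligible`, `max_slice_area_cm2`, `volume_cm3`.
#' @export
roi_eligibility <- function(mask, area_min_cm2 = 3, volume_min_cm3 = 6) {
  stopifnot(inherits(mask, "roi_mask"))
  m <- mask$mask
  if (!any(m)) stop("mask is empty", call. = FALSE)
  vd <- mask$voxel_dims
  slice_counts <- apply(m, 3, sum)
  area_cm2 <- max(slice_counts) * vd[1] * vd[2] / 100   # mm^2 -> cm^2
  vol_cm3 <- sum(m) * prod(vd) / 1000                   # mm^3 -> cm^3
  tibble::tibble(
    eligible = area_cm2 >= area_min_cm2 && vol_cm3 >= volume_min_cm3,
    max_slice_area_cm2 = area_cm2,
    volume_cm3 = vol_cm3
  )
}

#' Sample a case-level feature cohort from reference group statistics
#'
#' Draws per-case whole-tumor histogram-feature values directly from the
#' per-group normal distributions (mean, between-case SD) of a reference
#' table, bypassing image synthesis. This gives the statistics layer cohorts
#' with exactly the published group structure. Values carry the reference
#' table's display units.
#'
#' @param groups Named integer vector mapping group label to number of
#'   cases; `NULL` uses the `n_cases` recorded in the reference table.
#' @param reference A reference tibble as from [tumor_group_reference()].
#' @param parameters,features Optional character filters on which
#'   parameter/feature rows to generate.
#' @param seed Optional integer seed.
#' @return A tibble `case_id`, `group`, `parameter`, `feature`, `value`.
#' @examples
#' cohort <- generate_feature_cohort(c(NB = 11, W = 8),
#'   parameters = "f", features = "mean", seed = 1)
#' @export
generate_feature_cohort <- function(groups = NULL,
                                    reference = tumor_group_reference(),
                                    parameters = NULL, features = NULL,
                                    seed = NULL) {
  if (is.null(groups)) {
    g <- dplyr::distinct(reference, .data$group, .data$n_cases)
    groups <- stats::setNames(g$n_cases, g$group)
  }
  unknown <- setdiff(names(groups), unique(reference$group))
  if (length(unknown)) {
    stop("unknown group label(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  stopifnot(all(groups >= 1))
  ref <- reference
  if (!is.null(parameters)) ref <- dplyr::filter(ref, .data$parameter %in% !!parameters)
  if (!is.null(features)) ref <- dplyr::filter(ref, .data$feature %in% !!features)
  ref <- dplyr::arrange(ref, .data$group, .data$parameter, .data$feature)

  with_local_seed(seed, {
    purrr::map_dfr(names(groups), function(gl) {
      n <- unname(groups[[gl]])
      rows <- dplyr::filter(ref, .data$group == gl)
      purrr::pmap_dfr(rows, function(group, n_cases, parameter, feature, mean, sd) {
        tibble::tibble(
          case_id = sprintf("%s_%02d", gl, seq_len(n)),
          group = gl, parameter = parameter, feature = feature,
          value = stats::rnorm(n, mean, sd)
        )
      })
    })
  })
}

#' Simulate an imaging cohort of synthetic lesions
#'
#' For each case, case-level means of D, D* and f are drawn from the
#' reference group's between-case distribution (the `mean` feature rows,
#' converted to internal units), and a voxelwise within-lesion spread is set
#' from the group's interquartile range (IQR/1.349, a robust SD estimate).
#' Each case then becomes a Rician-noise phantom via [generate_phantom()].
#'
#' @param groups Named integer vector: group label -> number of cases.
#' @param reference Reference statistics table, display units.
#' @param axes,voxel_dims,S0,snr Imaging geometry and noise, passed to
#'   [lesion_spec()].
#' @param bvals b-value scheme.
#' @param seed Optional integer seed governing the whole cohort.
#' @return A list of class `"imaging_cohort"`: `cases` (tibble `case_id`,
#'   `group`) and `phantoms` (named list of [generate_phantom()] results).
#' @export
simulate_imaging_cohort <- function(groups = c(NB = 4, W = 4),
                                    reference = tumor_group_reference(),
                                    axes = c(10, 10, 4),
                                    voxel_dims = c(1, 1, 5),
                                    S0 = 1000, snr = 50,
                                    bvals = default_bvals(),
                                    seed = NULL) {
  unknown <- setdiff(names(groups), unique(reference$group))
  if (length(unknown)) {
    stop("unknown group label(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  ref_stat <- function(gl, par, feat, col = "mean") {
    r <- dplyr::filter(reference, .data$group == gl, .data$parameter == par,
                       .data$feature == feat)
    r[[col]][1]
  }
  with_local_seed(seed, {
    cases <- tibble::tibble(
      case_id = unlist(purrr::imap(groups, function(n, gl) sprintf("%s_%02d", gl, seq_len(n)))),
      group = rep(names(groups), unname(groups))
    )
    phantoms <- purrr::map2(cases$case_id, cases$group, function(cid, gl) {
      # case-level means (display units -> internal), redrawn into validity
      d_mu <- sample_trunc(1, ref_stat(gl, "D", "mean"), ref_stat(gl, "D", "mean", "sd"),
                           "normal", lower = 0) * 1e-6
      ds_mu <- sample_trunc(1, ref_stat(gl, "Dstar", "mean"), ref_stat(gl, "Dstar", "mean", "sd"),
                            "normal", lower = 0) * 1e-6
      f_mu <- min(max(stats::rnorm(1, ref_stat(gl, "f", "mean"), ref_stat(gl, "f", "mean", "sd")) / 100, 0), 1)
      iqr_sd <- function(par, scale) {
        (ref_stat(gl, par, "p75") - ref_stat(gl, par, "p25")) / 1.349 * scale
      }
      spec <- lesion_spec(
        axes = axes, voxel_dims = voxel_dims,
        d = list(location = d_mu, scale = iqr_sd("D", 1e-6)),
        dstar = list(location = ds_mu, scale = iqr_sd("Dstar", 1e-6)),
        f = list(location = f_mu, scale = iqr_sd("f", 1e-2)),
        S0 = S0, snr = snr
      )
      generate_phantom(spec, bvals)
    })
    names(phantoms) <- cases$case_id
    structure(list(cases = cases, phantoms = phantoms),
              class = "imaging_cohort")
  })
}
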