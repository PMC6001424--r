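#' Extract whole-lesion voxel values from a parameter map
#'
#' Returns the finite in-mask values of one 3D map, dropping voxels whose
#' fit flags match `exclude_flags` (by default those excluded for
#' non-positive signal). The result is an unordered value sample; every
#' downstream feature is order-independent.
#'
#' @param map 3D numeric array.
#' @param mask A [roi_mask()] (or 3D logical array) of matching dimensions.
#' @param flags Optional 3D integer flag array (see [fit_flags()]).
#' @param exclude_flags Integer bitmask of flags to drop.
#' @return Numeric vector of voxel values.
#' @export
extract_roi_values <- function(map, mask, flags = NULL,
                               exclude_flags = fit_flags()[["excluded_nonpositive_signal"]]) {
  m <- if (inherits(mask, "roi_mask")) mask$mask else mask
  if (!identical(dim(map), dim(m))) {
    stop("map and mask dimensions differ", call. = FALSE)
  }
  keep <- m & is.finite(map)
  if (!is.null(flags)) {
    keep <- keep & !is.na(flags) & bitwAnd(flags, as.integer(exclude_flags)) == 0L
  }
  vals <- map[keep]
  if (length(vals) == 0) {
    stop("no usable voxels in the mask", call. = FALSE)
  }
  vals
}

# Fixed-width bin edges covering the value range; degenerate (zero-width)
# ranges get a single unit-width bin.
bin_edges_for <- function(values, bin_width) {
  lo <- floor(min(values) / bin_width) * bin_width
  hi <- ceiling(max(values) / bin_width) * bin_width
  if (hi <= lo) hi <- lo + bin_width
  seq(lo, hi, by = bin_width)
}

#' Max-normalized histogram of a value sample
#'
#' Bins the values on a fixed-width grid and divides the counts by the
#' maximum count, so lesions of different sizes share a common \[0, 1\]
#' frequency scale for display and group averaging. A zero-width value
#' range yields a single occupied bin of height 1.
#'
#' @param values Numeric vector, length >= 1.
#' @param bin_width Bin width in the units of `values`.
#' @param edges Optional explicit bin edges (strictly increasing); when
#'   given, `bin_width` is ignored. Values falling outside are counted in
#'   the end bins.
#' @return A tibble of class `"ivim_histogram"`: `bin_start`, `bin_mid`,
#'   `bin_end`, `count`, `norm_count` (max 1).
#' @export
compute_histogram <- function(values, bin_width = 1, edges = NULL) {
  stopifnot(length(values) >= 1, all(is.finite(values)))
  if (is.null(edges)) {
    edges <- bin_edges_for(values, bin_width)
  } else if (is.unsorted(edges, strictly = TRUE)) {
    stop("bin edges must be strictly increasing", call. = FALSE)
  }
  cut_idx <- findInterval(values, edges, rightmost.closed = TRUE,
                          all.inside = TRUE)
  counts <- tabulate(cut_idx, nbins = length(edges) - 1)
  out <- tibble::tibble(
    bin_start = edges[-length(edges)],
    bin_mid = (edges[-length(edges)] + edges[-1]) / 2,
    bin_end = edges[-1],
    count = counts,
    norm_count = counts / max(counts)
  )
  class(out) <- c("ivim_histogram", class(out))
  out
}

#' First-order histogram features of a value sample
#'
#' The nine whole-lesion statistics: mean, median, 5th/25th/75th/90th
#' percentiles (linear interpolation between order statistics), skewness
#' (Fisher-Pearson standardized third moment), kurtosis (Pearson
#' standardized fourth moment, so a normal distribution scores 3, not 0),
#' and Shannon entropy in bits of the probability-normalized fixed-width
#' bin frequencies. Location features are computed on the raw voxel
#' values, not on binned data; only entropy depends on the binning.
#'
#' @param values Numeric vector, length >= 8 (percentiles below that are
#'   not meaningful).
#' @param bin_width Bin width for the entropy histogram, in value units.
#' @return One-row tibble: `mean`, `median`, `p5`, `p25`, `p75`, `p90`,
#'   `skewness`, `kurtosis`, `entropy`. Shape moments are `NA` for
#'   all-identical samples (zero variance).
#' @examples
#' histogram_features(rnorm(1000), bin_width = 0.1)
#' @export
histogram_features <- function(values, bin_width = 1) {
  stopifnot(all(is.finite(values)))
  if (length(values) < 8) {
    stop("need at least 8 values for stable percentile features", call. = FALSE)
  }
  q <- stats::quantile(values, c(0.05, 0.25, 0.5, 0.75, 0.90), names = FALSE,
                       type = 7)
  if (stats::sd(values) == 0) {
    skew <- NA_real_
    kurt <- NA_real_
  } else {
    skew <- e1071::skewness(values, type = 1)
    kurt <- e1071::kurtosis(values, type = 1) + 3  # Pearson convention
  }
  h <- compute_histogram(values, bin_width = bin_width)
  p <- h$count / sum(h$count)
  p <- p[p > 0]
  tibble::tibble(
    mean = mean(values), median = q[3],
    p5 = q[1], p25 = q[2], p75 = q[4], p90 = q[5],
    skewness = skew, kurtosis = kurt,
    entropy = -sum(p * log2(p))
  )
}

#' Whole-lesion feature table of an IVIM parameter-map set
#'
#' Extracts the ROI values of each parameter map, rescales them to display
#' units (ADC/D/D* in 1e-6 mm^2/s, f in percent), and computes the nine
#' first-order features per parameter using the per-parameter default bin
#' widths for entropy. Voxels flagged `excluded_nonpositive_signal` are
#' dropped; D* additionally drops voxels with no D* estimate.
#'
#' @param maps A [parameter_maps()] object.
#' @param mask A [roi_mask()].
#' @param case_id,group Optional identifiers carried into the output.
#' @param bin_widths Named numeric, entropy bin widths in display units;
#'   defaults to [default_bin_width()].
#' @return A tidy tibble: `case_id`, `group`, `parameter`, `feature`,
#'   `value` (display units).
#' @export
ivim_features <- function(maps, mask, case_id = NA_character_,
                          group = NA_character_,
                          bin_widths = default_bin_width()) {
  stopifnot(inherits(maps, "parameter_maps"))
  purrr::map_dfr(c("ADC", "D", "Dstar", "f"), function(par) {
    map <- switch(par, ADC = maps$adc, D = maps$d, Dstar = maps$dstar,
                  f = maps$f)
    vals <- extract_roi_values(map, mask, flags = maps$flags)
    vals <- vals * display_scale(par)
    feats <- histogram_features(vals, bin_width = bin_widths[[par]])
    tidyr::pivot_longer(feats, dplyr::everything(),
                        names_to = "feature", values_to = "value") |>
      dplyr::mutate(case_id = case_id, group = group, parameter = par,
                    .before = 1)
  })
}

#' Average histogram across cases of one group
#'
#' Per-bin mean and sample standard deviation of max-normalized histograms
#' sharing one bin grid, the group-level summary used to compare histogram
#' shapes between tumor types.
#'
#' @param histograms A list of [compute_histogram()] results on identical
#'   bin edges.
#' @return A tibble: `bin_mid`, `mean`, `sd` (sd is 0 for a single case).
#' @export
average_group_histogram <- function(histograms) {
  stopifnot(length(histograms) >= 1)
  ref <- histograms[[1]]
  for (h in histograms[-1]) {
    if (!isTRUE(all.equal(h$bin_start, ref$bin_start)) ||
        !isTRUE(all.equal(h$bin_end, ref$bin_end))) {
      stop("histograms must share identical bin grids", call. = FALSE)
    }
  }
  mat <- vapply(histograms, function(h) h$norm_count, numeric(nrow(ref)))
  mat <- matrix(mat, nrow = nrow(ref))
  tibble::tibble(
    bin_mid = ref$bin_mid,
    mean = rowMeans(mat),
    sd = if (ncol(mat) == 1) rep(0, nrow(mat)) else apply(mat, 1, stats::sd)
  )
}
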