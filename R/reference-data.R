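#' Reference group statistics for pediatric renal-bed tumor types
#'
#' Published per-group summary statistics (mean and between-case SD of each
#' whole-tumor first-order histogram feature) for the three major malignant
#' tumor types in the renal bed: hepatoblastoma (`HB`, n = 4), neuroblastoma
#' (`NB`, n = 11) and Wilms' tumor (`W`, n = 8). These parameterize the
#' synthetic cohort generators.
#'
#' Units follow the conventional reporting scale: `ADC`, `D` and `Dstar`
#' location features in 1e-6 mm^2/s, `f` in percent; `kurtosis` and
#' `skewness` dimensionless; `entropy` in bits.
#'
#' @return A tibble with columns `group`, `n_cases`, `parameter`
#'   (`ADC`, `D`, `Dstar`, `f`), `feature` (`mean`, `median`, `p5`, `p25`,
#'   `p75`, `p90`, `kurtosis`, `skewness`, `entropy`), `mean`, `sd`.
#' @examples
#' dplyr::filter(tumor_group_reference(), parameter == "f", feature == "mean")
#' @export
tumor_group_reference <- function() {
  path <- system.file("extdata", "tumor_group_stats.csv",
                      package = "ivimhist", mustWork = TRUE)
  tbl <- utils::read.csv(path, stringsAsFactors = FALSE)
  tibble::as_tibble(tbl)
}

# Display-unit scale factors between the internal computational units
# (diffusivities in mm^2/s, f as a fraction) and the reporting units
# (1e-6 mm^2/s, percent). Shape statistics are unitless either way.
display_scale <- function(parameter) {
  unname(c(ADC = 1e6, D = 1e6, Dstar = 1e6, f = 100)[parameter])
}

#' Default histogram bin widths per parameter
#'
#' Fixed absolute bin widths, in display units, used when binning voxel
#' values for entropy and for the normalized display histograms. Fixed
#' widths keep entropy comparable across lesions of different size and
#' value range: 10 (1e-6 mm^2/s) for `ADC` and `D`, 500 (1e-6 mm^2/s) for
#' `Dstar`, and 0.5 percentage points for `f`.
#'
#' @param parameter Character vector of parameter names.
#' @return Named numeric vector of bin widths in display units.
#' @export
default_bin_width <- function(parameter = c("ADC", "D", "Dstar", "f")) {
  widths <- c(ADC = 10, D = 10, Dstar = 500, f = 0.5)
  bad <- setdiff(parameter, names(widths))
  if (length(bad)) stop("unknown parameter: ", paste(bad, collapse = ", "), call. = FALSE)
  widths[parameter]
}
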