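new_group_comparison <- function(method, statistic, df, p_value, group_labels,
                                 n, post_hoc = NULL) {
  structure(
    list(method = method, statistic = statistic, df = df, p_value = p_value,
         group_labels = group_labels, n = n, post_hoc = post_hoc),
    class = "group_comparison"
  )
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g (groups: %s)\n",
              x$method, x$statistic, x$p_value,
              paste(x$group_labels, collapse = ", ")))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.group_comparison <- function(x, ...) {
  tibble::tibble(method = x$method, statistic = x$statistic,
                 df = if (is.null(x$df)) NA_real_ else x$df,
                 p_value = x$p_value)
}

#' @export
glance.group_comparison <- function(x, ...) tidy(x)

#' Kruskal-Wallis comparison of a feature across groups
#'
#' Rank-based omnibus test (tie-corrected H statistic, chi-square reference
#' with k - 1 degrees of freedom) of one feature across three or more
#' groups.
#'
#' @param data A data frame.
#' @param value,group Columns holding the feature values and group labels
#'   (tidy evaluation).
#' @return A `"group_comparison"` object with `tidy()`/`glance()` methods.
#' @examples
#' d <- data.frame(g = rep(c("a", "b", "c"), each = 3),
#'                 y = c(1, 2, 3, 11, 12, 13, 21, 22, 23))
#' tidy(kruskal_wallis(d, y, g))
#' @export
kruskal_wallis <- function(data, value, group) {
  v <- dplyr::pull(data, {{ value }})
  g <- factor(dplyr::pull(data, {{ group }}))
  stopifnot(nlevels(g) >= 2, all(table(g) >= 2))
  if (stats::sd(v) == 0) {
    warning("all values identical; p set to 1")
    return(new_group_comparison("Kruskal-Wallis", 0, nlevels(g) - 1, 1,
                                levels(g), as.integer(table(g))))
  }
  kt <- stats::kruskal.test(v, g)
  new_group_comparison("Kruskal-Wallis", unname(kt$statistic),
                       unname(kt$parameter), kt$p.value, levels(g),
                       as.integer(table(g)))
}

#' Dunn's post-hoc pairwise comparisons
#'
#' After a significant Kruskal-Wallis test, identifies which group pairs
#' differ: z statistics from the pooled-rank means with tie correction,
#' two-sided normal p-values, and Bonferroni adjustment over the pairwise
#' family (multiplied by the number of comparisons, capped at 1). Both raw
#' and adjusted p-values are reported.
#'
#' @inheritParams kruskal_wallis
#' @param adjust Adjustment method passed to [stats::p.adjust()];
#'   default `"bonferroni"`.
#' @return A tibble: `group1`, `group2`, `z`, `p_value`, `p_adjusted`.
#' @export
dunn_posthoc <- function(data, value, group, adjust = "bonferroni") {
  v <- dplyr::pull(data, {{ value }})
  g <- factor(dplyr::pull(data, {{ group }}))
  g <- droplevels(g)
  counts <- table(g)
  if (any(counts == 0)) warning("dropping empty groups")
  r <- rank(v)
  N <- length(v)
  ties <- table(v)
  tie_corr <- sum(ties^3 - ties) / (12 * (N - 1))
  rank_means <- tapply(r, g, mean)
  pairs <- utils::combn(levels(g), 2)
  z <- p <- numeric(ncol(pairs))
  for (i in seq_len(ncol(pairs))) {
    a <- pairs[1, i]; b <- pairs[2, i]
    se <- sqrt((N * (N + 1) / 12 - tie_corr) *
                 (1 / counts[[a]] + 1 / counts[[b]]))
    z[i] <- (rank_means[[a]] - rank_means[[b]]) / se
    p[i] <- 2 * stats::pnorm(-abs(z[i]))
  }
  tibble::tibble(
    group1 = pairs[1, ], group2 = pairs[2, ], z = z, p_value = p,
    p_adjusted = stats::p.adjust(p, method = adjust)
  )
}

#' Mann-Whitney U comparison of two groups
#'
#' Two-sided rank-sum test between exactly two groups: exact p for small
#' tie-free samples, normal approximation with tie correction otherwise.
#' The reported U counts wins of the first group level (plus half-ties);
#' U_A + U_B = n_A * n_B.
#'
#' @inheritParams kruskal_wallis
#' @return A `"group_comparison"` object; `statistic` is U for the first
#'   group level.
#' @examples
#' d <- data.frame(g = rep(c("a", "b"), each = 3), y = c(1, 2, 3, 4, 5, 6))
#' tidy(mann_whitney(d, y, g))
#' @export
mann_whitney <- function(data, value, group) {
  v <- dplyr::pull(data, {{ value }})
  g <- factor(dplyr::pull(data, {{ group }}))
  if (nlevels(g) != 2) stop("mann_whitney needs exactly two groups", call. = FALSE)
  x <- v[g == levels(g)[1]]
  y <- v[g == levels(g)[2]]
  if (length(unique(v)) == 1) {
    return(new_group_comparison("Mann-Whitney U", length(x) * length(y) / 2,
                                NULL, 1, levels(g), c(length(x), length(y))))
  }
  wt <- suppressWarnings(stats::wilcox.test(x, y))
  new_group_comparison("Mann-Whitney U", unname(wt$statistic), NULL,
                       wt$p.value, levels(g), c(length(x), length(y)))
}

#' ROC analysis with Youden-optimal cutoff
#'
#' Empirical ROC curve of a continuous feature against a binary class
#' label: trapezoidal AUC (identical to the Mann-Whitney U statistic
#' divided by n1*n2), DeLong confidence interval, a two-sided p-value for
#' AUC != 0.5 (rank-sum test), and the cutoff maximizing the Youden index
#' (sensitivity + specificity - 1). Candidate cutoffs lie midway between
#' consecutive observed values; Youden ties are broken toward higher
#' specificity, then toward the lower cutoff.
#'
#' @param data A data frame.
#' @param score,label Columns holding the feature and the class label.
#' @param positive The label value treated as the positive class.
#' @param direction `"higher"` if larger scores indicate the positive
#'   class (default), `"lower"` for the reverse.
#' @param conf_level Confidence level of the DeLong interval.
#' @return An object of class `"roc_result"` with fields `auc`, `ci_low`,
#'   `ci_high`, `cutoff`, `sensitivity`, `specificity` (percent),
#'   `p_value`, `n_pos`, `n_neg` and the full `curve` tibble; has
#'   `tidy()`, `glance()` and `autoplot()` methods.
#' @examples
#' d <- data.frame(s = c(1, 2, 3, 4), y = c("n", "p", "n", "p"))
#' tidy(roc_youden(d, s, y, positive = "p"))
#' @export
roc_youden <- function(data, score, label, positive,
                       direction = c("higher", "lower"),
                       conf_level = 0.95) {
  direction <- match.arg(direction)
  s <- dplyr::pull(data, {{ score }})
  y <- dplyr::pull(data, {{ label }})
  pos <- y == positive
  if (!any(pos) || all(pos)) stop("both classes must be present", call. = FALSE)
  sgn <- if (direction == "higher") 1 else -1
  sw <- sgn * s

  u <- sort(unique(sw))
  cand <- c(u[1] - 1, (u[-length(u)] + u[-1]) / 2, u[length(u)] + 1)
  sens <- vapply(cand, function(t) mean(sw[pos] >= t), numeric(1))
  spec <- vapply(cand, function(t) mean(sw[!pos] < t), numeric(1))
  curve <- tibble::tibble(cutoff = sgn * cand, sensitivity = sens,
                          specificity = spec)

  # trapezoidal AUC over the empirical curve (ties give diagonal segments)
  ord <- order(1 - spec, sens)
  fpr <- (1 - spec)[ord]; tpr <- sens[ord]
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)

  youden <- sens + spec - 1
  best <- order(-youden, -spec, cand)[1]

  roc_obj <- pROC::roc(
    response = factor(pos, levels = c(FALSE, TRUE)), predictor = sw,
    levels = c(FALSE, TRUE), direction = "<", quiet = TRUE
  )
  ci <- as.numeric(suppressWarnings(
    pROC::ci.auc(roc_obj, conf.level = conf_level, method = "delong")))
  pv <- suppressWarnings(stats::wilcox.test(sw[pos], sw[!pos]))$p.value

  structure(
    list(auc = auc, ci_low = max(0, ci[1]), ci_high = min(1, ci[3]),
         cutoff = sgn * cand[best],
         sensitivity = 100 * sens[best], specificity = 100 * spec[best],
         p_value = pv, n_pos = sum(pos), n_neg = sum(!pos),
         positive = as.character(positive), direction = direction,
         curve = curve),
    class = "roc_result"
  )
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf(
    "ROC (positive = %s, n = %d/%d): AUC = %.3f [%.3f, %.3f], p = %.3g\n",
    x$positive, x$n_pos, x$n_neg, x$auc, x$ci_low, x$ci_high, x$p_value))
  cat(sprintf("Youden cutoff = %.4g: sensitivity %.1f%%, specificity %.1f%%\n",
              x$cutoff, x$sensitivity, x$specificity))
  invisible(x)
}

#' @export
tidy.roc_result <- function(x, ...) {
  tibble::tibble(auc = x$auc, ci_low = x$ci_low, ci_high = x$ci_high,
                 cutoff = x$cutoff, sensitivity = x$sensitivity,
                 specificity = x$specificity, p_value = x$p_value)
}

#' @export
glance.roc_result <- function(x, ...) tidy(x)

#' Voxelwise Pearson correlation between two parameter maps
#'
#' Correlates two co-registered maps over the in-mask voxels, optionally
#' restricted to voxels whose perfusion fraction lies inside a band (in
#' percent) — used to probe whether high-f regions behave like artifact or
#' pathology. Fewer than 3 usable voxels, or zero variance in either map,
#' yields a missing `r` with a warning.
#'
#' @param f_map 3D perfusion-fraction map (fraction scale).
#' @param other_map 3D map to correlate against, same dimensions.
#' @param mask A [roi_mask()] or 3D logical array.
#' @param f_band Optional numeric length-2, f band in percent
#'   (e.g. `c(25, 40)`); `NULL` uses the whole mask.
#' @return One-row tibble: `r`, `n_voxels`, `band_low`, `band_high`.
#' @export
voxelwise_pearson <- function(f_map, other_map, mask, f_band = NULL) {
  m <- if (inherits(mask, "roi_mask")) mask$mask else mask
  stopifnot(identical(dim(f_map), dim(other_map)),
            identical(dim(f_map), dim(m)))
  keep <- m & is.finite(f_map) & is.finite(other_map)
  if (!is.null(f_band)) {
    stopifnot(length(f_band) == 2, f_band[1] < f_band[2])
    fp <- 100 * f_map
    keep <- keep & fp >= f_band[1] & fp <= f_band[2]
  }
  x <- f_map[keep]; y <- other_map[keep]
  band <- if (is.null(f_band)) c(NA_real_, NA_real_) else f_band
  if (length(x) < 3) {
    warning("fewer than 3 voxels after filtering; correlation is missing")
    r <- NA_real_
  } else if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("zero variance in a map; correlation is missing")
    r <- NA_real_
  } else {
    r <- stats::cor(x, y)
  }
  tibble::tibble(r = r, n_voxels = length(x),
                 band_low = band[1], band_high = band[2])
}

#' Groupwise comparison of every parameter/feature combination
#'
#' Runs the omnibus Kruskal-Wallis test (3+ groups) or the Mann-Whitney U
#' test (2 groups) on each parameter x feature cell of a tidy feature
#' table, with Bonferroni adjustment across the nine features within each
#' parameter. For 3+ groups, Dunn's pairwise post-hoc results (Bonferroni
#' over pairs) are attached per cell.
#'
#' @param features Tidy tibble with columns `case_id`, `group`,
#'   `parameter`, `feature`, `value`.
#' @return A list: `omnibus` (tibble `parameter`, `feature`, `method`,
#'   `statistic`, `p_value`, `p_adjusted`) and `post_hoc` (tibble of Dunn
#'   comparisons, empty for two groups).
#' @export
compare_feature_groups <- function(features) {
  stopifnot(all(c("group", "parameter", "feature", "value") %in% names(features)))
  cells <- dplyr::distinct(features, .data$parameter, .data$feature)
  n_groups <- length(unique(features$group))
  omni <- purrr::pmap_dfr(cells, function(parameter, feature) {
    d <- features[features$parameter == parameter & features$feature == feature, ]
    cmp <- if (n_groups >= 3) {
      kruskal_wallis(d, .data$value, .data$group)
    } else {
      mann_whitney(d, .data$value, .data$group)
    }
    dplyr::mutate(tidy(cmp), parameter = parameter, feature = feature,
                  .before = 1)
  })
  omni <- omni |>
    dplyr::group_by(.data$parameter) |>
    dplyr::mutate(p_adjusted = stats::p.adjust(.data$p_value, "bonferroni")) |>
    dplyr::ungroup()
  post <- if (n_groups >= 3) {
    purrr::pmap_dfr(cells, function(parameter, feature) {
      d <- features[features$parameter == parameter & features$feature == feature, ]
      dplyr::mutate(dunn_posthoc(d, .data$value, .data$group),
                    parameter = parameter, feature = feature, .before = 1)
    })
  } else {
    tibble::tibble()
  }
  list(omnibus = omni, post_hoc = post)
}

#' ROC table over every parameter/feature combination
#'
#' Diagnostic performance of each parameter x feature cell in
#' discriminating a positive from a negative group: one [roc_youden()] row
#' per cell.
#'
#' @inheritParams compare_feature_groups
#' @param positive,negative Group labels of the two classes.
#' @param direction Passed to [roc_youden()].
#' @return A tibble: `parameter`, `feature`, `auc`, `ci_low`, `ci_high`,
#'   `cutoff`, `sensitivity`, `specificity`, `p_value`.
#' @export
roc_table <- function(features, positive, negative,
                      direction = "higher") {
  d <- features[features$group %in% c(positive, negative), ]
  cells <- dplyr::distinct(d, .data$parameter, .data$feature)
  purrr::pmap_dfr(cells, function(parameter, feature) {
    cell <- d[d$parameter == parameter & d$feature == feature, ]
    r <- roc_youden(cell, .data$value, .data$group, positive = positive,
                    direction = direction)
    dplyr::mutate(tidy(r), parameter = parameter, feature = feature,
                  .before = 1)
  })
}
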