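test_that("ROI value extraction honors mask and flags", {
  m <- block_mask(10, 1)
  map <- array(7, dim(m$mask))
  expect_equal(extract_roi_values(map, m), rep(7, 10))
  # flagged voxels are dropped
  flags <- array(NA_integer_, dim(m$mask))
  flags[m$mask] <- 0L
  idx <- which(m$mask)[1:3]
  flags[idx] <- fit_flags()[["excluded_nonpositive_signal"]]
  expect_length(extract_roi_values(map, m, flags), 7)
  # clamped voxels are retained (only exclusion flags drop values)
  flags[idx] <- fit_flags()[["clamped_f"]]
  expect_length(extract_roi_values(map, m, flags), 10)
  expect_error(extract_roi_values(array(1, c(2, 2, 2)), m), "differ")
  empty <- roi_mask(array(FALSE, dim(m$mask)))
  expect_error(extract_roi_values(map, empty), "no usable voxels")
})

test_that("max-normalized histograms have unit peak", {
  h <- compute_histogram(rep(5, 20), bin_width = 1)
  expect_equal(sum(h$count > 0), 1)
  expect_equal(max(h$norm_count), 1)
  # invariant over random inputs
  set.seed(30)
  for (i in 1:10) {
    h <- compute_histogram(rnorm(200), bin_width = 0.25)
    expect_equal(max(h$norm_count), 1)
    expect_true(all(h$norm_count >= 0))
    expect_true(all(diff(h$bin_start) > 0))
  }
  # multinomial concentration: uniform draws fill 10 equal bins evenly
  set.seed(31)
  h <- compute_histogram(runif(1e5), edges = seq(0, 1, by = 0.1))
  expect_true(all(h$norm_count >= 0.8))
  expect_error(compute_histogram(1:5, edges = c(1, 3, 2)), "increasing")
})

test_that("first-order features use the documented conventions", {
  f <- histogram_features(as.numeric(1:10), bin_width = 1)
  expect_equal(f$median, 5.5)
  expect_equal(f$p25, 3.25)   # linear interpolation between order stats
  expect_equal(f$p75, 7.75)
  expect_equal(f$p5, quantile(1:10, 0.05, names = FALSE))
  # moment conventions on a large seeded normal sample
  set.seed(32)
  x <- rnorm(1e5)
  f <- histogram_features(x, bin_width = 0.1)
  expect_lt(abs(f$skewness), 0.05)
  expect_lt(abs(f$kurtosis - 3), 0.1)   # Pearson: normal -> 3
  # entropy closed form: two equal-mass bins = 1 bit
  f <- histogram_features(rep(c(0.25, 1.25), 50), bin_width = 1)
  expect_equal(f$entropy, 1)
  # a constant sample has 0 bits and undefined shape moments
  f <- histogram_features(rep(3, 10), bin_width = 1)
  expect_equal(f$entropy, 0)
  expect_true(is.na(f$skewness) && is.na(f$kurtosis))
  expect_error(histogram_features(1:5), "at least 8")
})

test_that("features are order-independent and affinely consistent", {
  set.seed(33)
  x <- rgamma(500, 2, 1)
  f1 <- histogram_features(x, bin_width = 0.2)
  f2 <- histogram_features(sample(x), bin_width = 0.2)
  expect_equal(f1, f2)
  # percentile ordering invariant
  expect_true(with(f1, p5 <= p25 && p25 <= median && median <= p75 &&
                     p75 <= p90))
  # location features are equivariant under y = a x + b; shape features
  # (with the bin width rescaled by a) are invariant
  a <- 2.5; b0 <- 10
  fa <- histogram_features(a * x + b0, bin_width = 0.2 * a)
  for (col in c("mean", "median", "p5", "p25", "p75", "p90")) {
    expect_equal(fa[[col]], a * f1[[col]] + b0, tolerance = 1e-12)
  }
  expect_equal(fa$skewness, f1$skewness, tolerance = 1e-12)
  expect_equal(fa$kurtosis, f1$kurtosis, tolerance = 1e-12)
  expect_equal(fa$entropy, f1$entropy, tolerance = 1e-12)
})

test_that("group-average histograms combine cases per bin", {
  edges <- seq(0, 10, by = 1)
  set.seed(34)
  h1 <- compute_histogram(runif(100, 0, 10), edges = edges)
  # single case: mean is the case itself, sd identically 0
  avg <- average_group_histogram(list(h1))
  expect_equal(avg$mean, h1$norm_count)
  expect_true(all(avg$sd == 0))
  # identical cases: sd identically 0
  avg <- average_group_histogram(list(h1, h1, h1))
  expect_true(all(avg$sd == 0))
  # two offset cases: per-bin sample SD equals |offset| / sqrt(2) * sqrt(2)
  h2 <- h1
  h2$norm_count <- h1$norm_count + 0.1
  avg <- average_group_histogram(list(h1, h2))
  expect_equal(avg$sd, rep(sd(c(0, 0.1)), nrow(h1)))
  expect_equal(avg$mean, h1$norm_count + 0.05)
  # mismatched grids are a format error
  h3 <- compute_histogram(runif(50), edges = seq(0, 1, by = 0.1))
  expect_error(average_group_histogram(list(h1, h3)), "identical bin grids")
})

test_that("whole-lesion feature tables are tidy and in display units", {
  spec <- lesion_spec(snr = Inf, axes = c(4, 4, 3),
                      d = list(location = 0.9e-3, scale = 0.1e-3),
                      dstar = list(location = 19e-3, scale = 5e-3),
                      f = list(location = 0.2, scale = 0.05))
  ph <- generate_phantom(spec, seed = 35)
  maps <- fit_volume(ph$dwi, ph$mask)
  feats <- ivim_features(maps, ph$mask, case_id = "c1", group = "NB")
  expect_equal(nrow(feats), 4 * 9)
  expect_setequal(unique(feats$parameter), c("ADC", "D", "Dstar", "f"))
  # display units: D near 900 (1e-6 mm^2/s), f near 20 (%)
  d_mean <- feats$value[feats$parameter == "D" & feats$feature == "mean"]
  f_mean <- feats$value[feats$parameter == "f" & feats$feature == "mean"]
  expect_gt(d_mean, 500); expect_lt(d_mean, 1500)
  expect_gt(f_mean, 10); expect_lt(f_mean, 30)
  # percentile ordering per parameter
  wide <- tidyr::pivot_wider(feats, names_from = "feature",
                             values_from = "value")
  expect_true(all(wide$p5 <= wide$p25 & wide$p25 <= wide$median &
                    wide$median <= wide$p75 & wide$p75 <= wide$p90))
})
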