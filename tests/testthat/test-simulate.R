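test_that("voxel parameter sampling honors its distributions and domain", {
  # zero-variance spec gives identical parameter sets
  spec0 <- lesion_spec(d = list(location = 0.9e-3, scale = 0),
                       dstar = list(location = 19e-3, scale = 0),
                       f = list(location = 0.2, scale = 0))
  p <- sample_voxel_params(spec0, 5)
  expect_equal(nrow(p), 5)
  expect_true(all(p$D == 0.9e-3 & p$Dstar == 19e-3 & p$f == 0.2))

  # law of large numbers: sample mean close to the location
  spec <- lesion_spec(f = list(location = 0.2, scale = 0.05))
  p <- sample_voxel_params(spec, 1e4, seed = 3)
  expect_gte(mean(p$f), 0.195)
  expect_lte(mean(p$f), 0.205)

  # clipping contract for f near its upper bound
  spec_hi <- lesion_spec(f = list(location = 0.99, scale = 0.5))
  p <- sample_voxel_params(spec_hi, 2000, seed = 4)
  expect_true(all(p$f <= 1 & p$f >= 0))

  # full invariants under a heavy-tailed draw
  spec_wide <- lesion_spec(d = list(location = 0.9e-3, scale = 1e-3),
                           dstar = list(location = 5e-3, scale = 20e-3))
  p <- sample_voxel_params(spec_wide, 5000, seed = 5)
  expect_true(all(p$D >= 0))
  expect_true(all(p$Dstar >= p$D))

  # degenerate (negative) scale is a configuration error
  expect_error(lesion_spec(d = list(location = 1e-3, scale = -1)),
               "non-negative")
})

test_that("Rician noise has the magnitude-model properties", {
  expect_identical(add_rician_noise(100, 0), 100)
  # Rayleigh limit: zero signal, mean sigma * sqrt(pi/2)
  x <- add_rician_noise(rep(0, 2e4), 1, seed = 6)
  expect_true(all(x >= 0))
  expect_equal(mean(x), sqrt(pi / 2), tolerance = 0.02)
  # general Rician mean against the numerical-integration oracle
  x <- add_rician_noise(rep(3, 2e4), 2, seed = 7)
  expect_equal(mean(x), rician_mean_oracle(3, 2), tolerance = 0.02)
})

test_that("phantoms are exact in the noiseless limit and reproducible", {
  spec <- lesion_spec(snr = Inf)
  ph <- generate_phantom(spec, seed = 8)
  idx <- which(ph$mask$mask)
  b <- ph$dwi$bvals
  # every in-mask voxel series equals the forward model of its ground truth
  pick <- idx[seq(1, length(idx), length.out = 25)]
  for (v in pick) {
    coord <- arrayInd(v, dim(ph$mask$mask))
    sig <- ph$dwi$signal[coord[1], coord[2], coord[3], ]
    truth <- ivim_params(S0 = 1000, D = ph$truth$d[v],
                         Dstar = ph$truth$dstar[v], f = ph$truth$f[v])
    expect_equal(sig, ivim_signal(truth, b), tolerance = 1e-12)
  }
  # determinism under a fixed seed
  ph2 <- generate_phantom(spec, seed = 8)
  expect_identical(ph$dwi$signal, ph2$dwi$signal)
  expect_identical(ph$truth$f, ph2$truth$f)
  # all magnitudes non-negative, background at zero without noise
  expect_true(all(ph$dwi$signal >= 0))
  expect_true(all(ph$dwi$signal[, , , 1][!ph$mask$mask] == 0))
})

test_that("noisy phantom b0 mean matches the integrated Rician mean", {
  spec <- lesion_spec(snr = 50,
                      d = list(location = 0.9e-3, scale = 0),
                      dstar = list(location = 19e-3, scale = 0),
                      f = list(location = 0.2, scale = 0))
  ph <- generate_phantom(spec, seed = 9)
  s0 <- ph$dwi$signal[, , , 1][ph$mask$mask]
  expected <- rician_mean_oracle(1000, 1000 / 50)
  expect_equal(mean(s0), expected, tolerance = 0.01 * expected)
})

test_that("lesion-size eligibility follows the area and volume thresholds", {
  # 400 voxels on one slice at 1 x 1 x 5 mm: area 4 cm^2, volume 2 cm^3
  e <- roi_eligibility(block_mask(400, 1))
  expect_equal(e$max_slice_area_cm2, 4)
  expect_equal(e$volume_cm3, 2)
  expect_false(e$eligible)
  # 300 voxels x 5 slices: area exactly 3 cm^2, volume 7.5 cm^3 (inclusive)
  e <- roi_eligibility(block_mask(300, 5))
  expect_equal(e$max_slice_area_cm2, 3)
  expect_equal(e$volume_cm3, 7.5)
  expect_true(e$eligible)
  # a single voxel can never qualify
  expect_false(roi_eligibility(block_mask(1, 1))$eligible)
  # empty masks are a domain error
  expect_error(roi_mask(array(FALSE, c(2, 2, 2))) |> roi_eligibility(),
               "empty")
})

test_that("feature cohorts reproduce the reference group structure", {
  cohort <- generate_feature_cohort(c(NB = 11, W = 8), parameters = "f",
                                    features = "mean", seed = 10)
  expect_equal(nrow(cohort), 19)
  expect_equal(sum(cohort$group == "NB"), 11)
  expect_equal(sum(cohort$group == "W"), 8)

  expect_error(generate_feature_cohort(c(XX = 3)), "unknown group")

  # determinism
  c2 <- generate_feature_cohort(c(NB = 11, W = 8), parameters = "f",
                                features = "mean", seed = 10)
  expect_identical(cohort, c2)

  # zero-variance reference makes all cases identical
  ref <- tumor_group_reference()
  ref$sd <- 0
  c0 <- generate_feature_cohort(c(NB = 3), reference = ref,
                                parameters = "f", features = "mean")
  expect_equal(length(unique(c0$value)), 1)
})

test_that("cohort sample means track the reference means", {
  ref <- tumor_group_reference()
  n <- 500
  cohort <- generate_feature_cohort(c(HB = n, NB = n, W = n), seed = 12)
  joined <- merge(
    aggregate(value ~ group + parameter + feature, cohort, mean), ref)
  z <- (joined$value - joined$mean) / (joined$sd / sqrt(n))
  # every cell within 4 standard errors; f-mean cells within 3
  expect_true(all(abs(z) < 4))
  fm <- joined$parameter == "f" & joined$feature == "mean"
  expect_true(all(abs(z[fm]) < 3))
})

test_that("imaging cohorts are reproducible and carry group labels", {
  co <- simulate_imaging_cohort(groups = c(NB = 2, W = 2), axes = c(4, 4, 3),
                                snr = 50, seed = 13)
  expect_equal(nrow(co$cases), 4)
  expect_setequal(unique(co$cases$group), c("NB", "W"))
  co2 <- simulate_imaging_cohort(groups = c(NB = 2, W = 2), axes = c(4, 4, 3),
                                 snr = 50, seed = 13)
  expect_identical(co$phantoms[[1]]$dwi$signal, co2$phantoms[[1]]$dwi$signal)
  expect_error(simulate_imaging_cohort(groups = c(QQ = 2)), "unknown group")
})
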