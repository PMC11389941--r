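test_that("configuration is validated", {
  expect_error(synthetic_config(n_patients = 0), class = "crlmrad_config_error")
  expect_error(synthetic_config(baseline_hazard = -1),
    class = "crlmrad_config_error")
  expect_error(synthetic_config(correlation = 1),
    class = "crlmrad_config_error")
  expect_error(synthetic_config(n_informative = 10, n_features = 5),
    class = "crlmrad_config_error")
  expect_error(generate_cohort(list(n_patients = 10)),
    class = "crlmrad_config_error")
})

test_that("null effects, no censoring: times are Exp(baseline_hazard)", {
  h0 <- 0.05
  cfg <- synthetic_config(n_patients = 400, true_betas = 0, crs_beta = 0,
    baseline_hazard = h0, censor_law = list(horizon = Inf, rate = 0),
    seed = 11)
  co <- generate_cohort(cfg)
  expect_equal(mean(co$patients$ttr_event), 1.0)
  m <- mean(co$patients$ttr_months)
  se <- (1 / h0) / sqrt(400)  # exponential: SD equals the mean
  expect_lt(abs(m - 1 / h0), 3 * se)
})

test_that("same config and seed reproduce the cohort byte-for-byte", {
  cfg <- synthetic_config(n_patients = 40, seed = 5)
  d1 <- file.path(tempdir(), "coh1"); d2 <- file.path(tempdir(), "coh2")
  write_cohort(generate_cohort(cfg), d1)
  write_cohort(generate_cohort(cfg), d2)
  for (f in c("lesions.csv", "patients.csv")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
})

test_that("generation-time linear predictor behaves as an oracle", {
  cfg <- synthetic_config(n_patients = 30, seed = 2)
  co <- generate_cohort(cfg)
  # recomputation matches the stored truth for every patient
  lp <- vapply(co$patients$patient_id, function(pid) {
    true_linear_predictor(patient_bundle(co, pid), cfg)
  }, numeric(1))
  expect_equal(unname(lp), co$latent$linear_predictor, tolerance = 1e-12)
  # centered predictor: all informative features at mean, CRS low -> 0
  b <- patient_bundle(co, "P0001")
  b$lesions[, sprintf("inf_%02d", 1:3)] <- 0
  b$clinical$crs_high <- FALSE
  expect_equal(true_linear_predictor(b, cfg), 0)
  # linearity: one informative feature at +1 SD
  b$lesions[which.max(b$lesions$volume_mm3), "inf_01"] <- 1
  expect_equal(true_linear_predictor(b, cfg), cfg$true_betas[1])
  # a bundle lacking this config's informative features is rejected
  b2 <- patient_bundle(co, "P0002")
  b2$lesions <- b2$lesions[, !grepl("^inf_", names(b2$lesions))]
  expect_error(true_linear_predictor(b2, cfg), class = "crlmrad_mismatch_error")
})

test_that("oracle predictor is at least as concordant as permuted scores", {
  cfg <- synthetic_config(n_patients = 300,
    censor_law = list(horizon = Inf, rate = 0), seed = 8)
  co <- generate_cohort(cfg)
  p <- co$patients
  c_oracle <- concordance_index(co$latent$linear_predictor, p$ttr_months,
    p$ttr_event)
  set.seed(1)
  for (i in 1:20) {
    c_perm <- concordance_index(sample(co$latent$linear_predictor),
      p$ttr_months, p$ttr_event)
    expect_gte(c_oracle, c_perm)
  }
})

test_that("event rate is monotone in the baseline hazard", {
  rates <- vapply(c(0.005, 0.02, 0.08, 0.3), function(h0) {
    co <- generate_cohort(synthetic_config(n_patients = 250,
      baseline_hazard = h0, seed = 21))
    mean(co$patients$ttr_event)
  }, numeric(1))
  expect_true(all(diff(rates) > -0.05))  # Monte-Carlo slack
})

test_that("censored records carry min(censor time, horizon), below the latent time", {
  co <- generate_cohort(synthetic_config(n_patients = 200, seed = 13))
  p <- co$patients
  lat <- co$latent
  cens <- p$ttr_event == 0
  expect_true(any(cens))
  expect_equal(p$ttr_months[cens],
    pmin(lat$ttr_censor, co$config$censor_law$horizon)[cens])
  expect_true(all(p$ttr_months[cens] < lat$ttr_latent[cens]))
})

test_that("cohort clinical profile supports the Fong score", {
  co <- generate_cohort(synthetic_config(n_patients = 150, seed = 4))
  p <- co$patients
  recomputed <- vapply(seq_len(nrow(p)), function(i) fong_crs(p[i, ]),
    integer(1))
  expect_identical(recomputed, p$crs)
  expect_true(all(p$crs %in% 0:5))
  expect_true(all(table(co$lesions$patient_id) >= 1))
  expect_true(all(co$lesions$volume_mm3 > 0))
})

test_that("phantom geometry is exact, seed-free, and validated", {
  # odd grid: the sphere center coincides with a voxel center, where the
  # lattice count is closest to the analytic volume
  spec <- phantom_spec(grid_shape = c(21, 21, 21), radii_mm = c(5, 5, 5),
    texture = list(amplitude = 0, scale_mm = 2))
  ph <- generate_phantom(spec, seed = 1)
  # homogeneous lesion: every in-mask voxel at the lesion mean
  expect_true(all(ph$image[ph$mask == 1] == 100))
  # voxelized sphere volume within 5% of (4/3) pi r^3
  expect_lt(abs(sum(ph$mask) - 4 / 3 * pi * 125) / (4 / 3 * pi * 125), 0.05)
  # geometry independent of seed; noise realization is not
  spec2 <- phantom_spec(grid_shape = c(20, 20, 20), radii_mm = c(5, 5, 5))
  a <- generate_phantom(spec2, seed = 1)
  b <- generate_phantom(spec2, seed = 2)
  expect_identical(as.integer(a$mask), as.integer(b$mask))
  expect_false(identical(a$image[a$mask == 1], b$image[b$mask == 1]))
  expect_error(phantom_spec(grid_shape = c(10, 10, 10), radii_mm = c(9, 2, 2)),
    class = "crlmrad_spec_error")
})

test_that("volumes round-trip through NIfTI with spacing intact", {
  ph <- generate_phantom(phantom_spec(grid_shape = c(12, 12, 12),
    radii_mm = c(3, 3, 3)), seed = 3)
  f <- tempfile(fileext = ".nii.gz")
  write_volume(ph$image, f)
  back <- read_volume(f)
  expect_equal(dim(back), dim(ph$image))
  expect_equal(attr(back, "spacing_mm"), attr(ph$image, "spacing_mm"))
  expect_equal(as.numeric(back), as.numeric(ph$image), tolerance = 1e-6)
})
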