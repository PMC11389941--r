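test_that("first-order statistics match their defining formulas", {
  cfg <- preprocess_config()
  f <- first_order_features(rep(42, 10), cfg)
  expect_equal(unname(f["variance"]), 0)
  expect_equal(unname(f["entropy"]), 0)
  expect_equal(unname(f["skewness"]), 0)
  f2 <- first_order_features(c(-100, 200), cfg)
  expect_equal(unname(f2["range"]), 300)
  expect_equal(unname(f2["mean"]), 50)
  # random sample against direct formula evaluation
  set.seed(7)
  v <- runif(500, -100, 200)
  f3 <- first_order_features(v, cfg)
  mu <- sum(v) / 500
  m2 <- sum((v - mu)^2) / 500
  expect_equal(unname(f3["mean"]), mu, tolerance = 1e-9)
  expect_equal(unname(f3["variance"]), m2, tolerance = 1e-9)
  expect_equal(unname(f3["skewness"]), sum((v - mu)^3) / 500 / m2^1.5,
    tolerance = 1e-9)
  expect_equal(unname(f3["kurtosis"]), sum((v - mu)^4) / 500 / m2^2,
    tolerance = 1e-9)
  expect_equal(unname(f3["energy"]), sum(v^2), tolerance = 1e-9)
  bins <- floor((v + 100) / 25) + 1
  ptab <- table(bins) / 500
  expect_equal(unname(f3["entropy"]), -sum(ptab * log2(ptab)),
    tolerance = 1e-9)
})

test_that("shape features of canonical solids match hand counts", {
  cube <- array(0L, dim = c(5, 5, 5))
  cube[2:4, 2:4, 2:4] <- 1L
  f <- shape_features(cube, c(1, 1, 1))
  expect_equal(unname(f["volume_mm3"]), 27)
  expect_equal(unname(f["surface_area_mm2"]), 54)
  expect_equal(unname(f["surface_to_volume_ratio"]), 2)
  expect_equal(unname(f["max_diameter_3d_mm"]), 2 * sqrt(3))
  single <- array(0L, dim = c(3, 3, 3))
  single[2, 2, 2] <- 1L
  expect_equal(unname(shape_features(single, c(1, 1, 1))["max_diameter_3d_mm"]), 0)
  # anisotropic spacing scales volume and faces accordingly
  f2 <- shape_features(cube, c(1, 2, 1))
  expect_equal(unname(f2["volume_mm3"]), 54)
})

test_that("GLCM features match exhaustive pair enumeration", {
  # 2x2x1 patch with bins {{1,2},{2,1}}
  bins <- array(c(1L, 2L, 2L, 1L), dim = c(2, 2, 1))
  mask <- array(1L, dim = c(2, 2, 1))
  got <- glcm_features(bins, mask, n_bins = 2)
  want <- oracle_glcm(bins, mask, 2)
  expect_equal(got, want, tolerance = 1e-12)
  # uniform region
  u <- glcm_features(array(3L, dim = c(3, 3, 3)), array(1L, dim = c(3, 3, 3)),
    n_bins = 5)
  expect_equal(unname(u["contrast"]), 0)
  expect_equal(unname(u["energy"]), 1)
  expect_equal(unname(u["correlation"]), 1)
  # contrast depends only on level differences: constant shift leaves it fixed
  set.seed(2)
  b1 <- array(sample(1:4, 27, TRUE), dim = c(3, 3, 3))
  m <- array(1L, dim = c(3, 3, 3))
  c1 <- glcm_features(b1, m, n_bins = 8)["contrast"]
  c2 <- glcm_features(b1 + 2L, m, n_bins = 8)["contrast"]
  expect_equal(c1, c2, tolerance = 1e-12)
  expect_error(glcm_features(array(1L, dim = c(1, 1, 1)),
    array(1L, dim = c(1, 1, 1))), class = "crlmrad_degenerate_error")
})

test_that("GLRLM features match exhaustive run enumeration", {
  # uniform bar along x: one run of length L per x-line
  bar <- array(1L, dim = c(4, 1, 1))
  mask <- array(1L, dim = c(4, 1, 1))
  f <- glrlm_features(bar, mask, n_bins = 2)
  expect_equal(f, oracle_glrlm(bar, mask, 2), tolerance = 1e-12)
  # strictly alternating line: all runs length 1, short-run emphasis 1
  alt <- array(rep(c(1L, 2L), 4), dim = c(8, 1, 1))
  fa <- glrlm_features(alt, array(1L, dim = c(8, 1, 1)), n_bins = 2)
  expect_equal(unname(fa["short_run_emphasis"]), 1)
  expect_equal(unname(fa["long_run_emphasis"]), 1)
  # random grids with holes in the mask
  set.seed(5)
  for (i in 1:5) {
    d <- c(sample(2:4, 1), sample(2:4, 1), sample(2:4, 1))
    bins <- array(sample(1:3, prod(d), TRUE), dim = d)
    mask <- array(rbinom(prod(d), 1, 0.8), dim = d)
    if (sum(mask) < 2) next
    expect_equal(glrlm_features(bins, mask, n_bins = 3),
      oracle_glrlm(bins, mask, 3), tolerance = 1e-12)
  }
})

test_that("extraction produces the declared catalog with channel prefixes", {
  cfg <- preprocess_config(log_sigmas_mm = c(1, 2))
  cat_names <- feature_catalog(cfg)
  # 5 shape + (10 first-order + 5 glcm + 5 glrlm) per channel, 3 channels
  expect_length(cat_names, 5 + 20 * 3)
  ph <- generate_phantom(phantom_spec(grid_shape = c(16, 16, 16),
    radii_mm = c(4, 4, 4), texture = list(amplitude = 0, scale_mm = 2)),
    seed = 1)
  rec <- extract_lesion(ph$image, ph$mask, cfg)
  expect_identical(names(rec$features), cat_names)
  # homogeneous lesion: zero texture contrast on the original channel
  expect_equal(unname(rec$features["original__glcm__contrast"]), 0)
  expect_equal(unname(rec$features["original__firstorder__variance"]), 0)
  expect_equal(rec$volume_mm3, unname(rec$features["shape__volume_mm3"]))
})

test_that("shape features ignore texture; texture ignores translation", {
  cfg <- preprocess_config(log_sigmas_mm = 1)
  base <- phantom_spec(grid_shape = c(18, 18, 18), radii_mm = c(4, 4, 4),
    texture = list(amplitude = 0, scale_mm = 2))
  loud <- phantom_spec(grid_shape = c(18, 18, 18), radii_mm = c(4, 4, 4),
    texture = list(amplitude = 20, scale_mm = 2))
  r1 <- extract_lesion(generate_phantom(base, 1)$image,
    generate_phantom(base, 1)$mask, cfg)
  r2 <- extract_lesion(generate_phantom(loud, 1)$image,
    generate_phantom(loud, 1)$mask, cfg)
  shp <- grepl("^shape__", names(r1$features))
  expect_equal(r1$features[shp], r2$features[shp])
  # translation invariance: same lesion shifted inside the grid
  sh1 <- phantom_spec(grid_shape = c(20, 20, 20), center_mm = c(8, 8, 8),
    radii_mm = c(3, 3, 3), texture = list(amplitude = 0, scale_mm = 2),
    background_hu = list(mean = 40, sd = 0))
  sh2 <- phantom_spec(grid_shape = c(20, 20, 20), center_mm = c(12, 12, 12),
    radii_mm = c(3, 3, 3), texture = list(amplitude = 0, scale_mm = 2),
    background_hu = list(mean = 40, sd = 0))
  p1 <- generate_phantom(sh1, 1); p2 <- generate_phantom(sh2, 1)
  f1 <- extract_lesion(p1$image, p1$mask, cfg)$features
  f2 <- extract_lesion(p2$image, p2$mask, cfg)$features
  expect_equal(f1, f2, tolerance = 1e-8)
})

test_that("feature tables are ingested with validation diagnostics", {
  tab <- data.frame(patient_id = c("P1", "P1"), lesion_id = c("L1", "L2"),
    volume_mm3 = c(100, 200), fA = c(1.5, 2.5), fB = c(0.1, 0.2))
  f <- tempfile(fileext = ".csv")
  write.csv(tab, f, row.names = FALSE)
  got <- ingest_feature_table(f)
  expect_equal(nrow(got), 2)
  expect_equal(got$fA, c(1.5, 2.5))
  # duplicate lesion key named in the error
  tab2 <- tab; tab2$lesion_id <- c("L1", "L1")
  write.csv(tab2, f, row.names = FALSE)
  expect_error(ingest_feature_table(f), "P1/L1",
    class = "crlmrad_integrity_error")
  # unknown column: error when strict, warning + pass-through when lenient
  write.csv(tab, f, row.names = FALSE)
  expect_error(ingest_feature_table(f, expected_features = "fA",
    strict = TRUE), class = "crlmrad_schema_error")
  expect_warning(got2 <- ingest_feature_table(f, expected_features = "fA"),
    "fB")
  expect_true("fB" %in% names(got2))
  # missing volume column
  tab3 <- tab[, setdiff(names(tab), "volume_mm3")]
  write.csv(tab3, f, row.names = FALSE)
  expect_error(ingest_feature_table(f), class = "crlmrad_schema_error")
  # non-numeric cell with row diagnostics
  tab4 <- tab; tab4$fA <- c("1.5", "oops")
  write.csv(tab4, f, row.names = FALSE)
  expect_error(ingest_feature_table(f), "fA", class = "crlmrad_schema_error")
})
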