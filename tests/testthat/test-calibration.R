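test_that("the original curve carries the vendor bulk anchors", {
  cur <- build_original_curve()
  a <- coef(cur)
  expect_equal(unname(a[, "hu"]), c(-1000, -75, 0, 204, 1170))
  expect_equal(a["soft_tissue", "hu"], c(hu = 0), ignore_attr = TRUE)
  expect_equal(a["adipose", "hu"], c(hu = -75), ignore_attr = TRUE)
  expect_true(all(diff(a[, "red"]) >= 0))
})

test_that("a noise-free cohort yields the exact optimized anchors", {
  co <- generate_cohort(3, coarse_spec(), jitter = 0.1, seed = 4,
                        classes = zero_noise_classes())
  stats <- lapply(co, function(p)
    class_hu_stats(p$ct, segment_classes(p$ct, threshold_scheme(opening_radius = 0))))
  cs <- cohort_class_stats(stats)
  opt <- derive_optimized_curve(cs)
  expect_equal(unname(coef(opt)[, "hu"]), c(-1000, -96, 37, 204, 1170))
  expect_equal(unname(coef(opt)[, "red"]), c(0.001, 0.95, 1.04, 1.1, 1.7))
  ct_curve <- derive_optimized_curve(cs, keep_sct_bone = FALSE)
  expect_equal(unname(coef(ct_curve)[, "hu"]), c(-1000, -96, 37, 219, 1000))
  # a single-patient cohort reproduces that patient's means
  cs1 <- cohort_class_stats(stats[1])
  expect_equal(cs1$mean_hu, stats[[1]]$mean_hu[match(cs1$class, stats[[1]]$class)])
})

test_that("curve evaluation interpolates, holds anchors and extrapolates safely", {
  cur <- calibration_curve(c(-1000, -96, 37, 204, 1170),
                           c(0.001, 0.95, 1.04, 1.1, 1.7))
  expect_identical(predict(cur, 204), 1.1)
  expect_identical(predict(cur, -1000), 0.001)
  # hand-computed midpoint of the two bone anchors
  expect_equal(predict(cur, (204 + 1170) / 2), (1.1 + 1.7) / 2)
  # below the lowest anchor: constant
  expect_identical(predict(cur, -4000), 0.001)
  # above the highest: linear continuation of the last segment ...
  slope <- (1.7 - 1.1) / (1170 - 204)
  expect_equal(predict(cur, 1300), 1.7 + slope * 130)
  # ... clamped at the configured maximum
  expect_identical(predict(cur, 1e6), 3)
  expect_error(predict(cur, c(0, NA)), "non-finite")
  # volumes in, volumes out
  v <- volume3d(array(c(-96, 37), c(2, 1, 1)))
  expect_equal(predict(cur, v)$values, array(c(0.95, 1.04), c(2, 1, 1)))
})

test_that("any valid curve evaluates continuously and monotonically", {
  set.seed(31)
  for (i in 1:20) {
    n <- sample(3:7, 1)
    hu <- sort(runif(n, -1000, 1500))
    red <- cumsum(runif(n, 0, 0.5))
    cur <- calibration_curve(hu, red, red_max = max(red) + 1)
    grid <- seq(-1500, 2500, length.out = 2000)
    y <- predict(cur, grid)
    expect_true(all(diff(y) >= -1e-12))
    expect_lt(max(abs(diff(y))), (max(red) + 1) * 4000 / 1999)  # no jumps
  }
})

test_that("serialization round-trips bit-exactly at 1000 probe points", {
  co <- generate_cohort(2, coarse_spec(), jitter = 0.1, seed = 6)
  stats <- lapply(co, function(p)
    class_hu_stats(p$ct, segment_classes(p$ct, threshold_scheme(opening_radius = 0))))
  cur <- derive_optimized_curve(cohort_class_stats(stats))
  path <- tempfile(fileext = ".csv")
  write_calibration(cur, path)
  back <- read_calibration(path)
  probes <- seq(-1200, 2000, length.out = 1000)
  expect_identical(predict(back, probes), predict(cur, probes))
  expect_identical(back$provenance, "optimized")
})

test_that("derived adipose and soft-tissue anchors recover the class means under noise", {
  # coarse voxels make cortical bone thinner than the opening ball, so the
  # unit-scale check segments without morphological cleanup
  co <- generate_cohort(10, coarse_spec(), jitter = 0.1, seed = 13,
                        classes = tissue_classes())
  stats <- lapply(co, function(p)
    class_hu_stats(p$ct, segment_classes(p$ct, threshold_scheme(opening_radius = 0))))
  cs <- cohort_class_stats(stats)
  opt <- derive_optimized_curve(cs)
  a <- coef(opt)
  se_a <- max(cs$se_mean[cs$class == "adipose"], 1e-6)
  se_s <- max(cs$se_mean[cs$class == "soft_tissue"], 1e-6)
  expect_lt(abs(a["adipose", "hu"] - (-96)), 3 * se_a + 0.05)
  expect_lt(abs(a["soft_tissue", "hu"] - 37), 3 * se_s + 0.05)
})

test_that("invalid curves are rejected", {
  expect_error(calibration_curve(c(0, 0), c(1, 2)), "duplicate|increasing")
  expect_error(calibration_curve(c(0, 10), c(1.1, 1.0)), "non-monotone")
  expect_error(calibration_curve(c(0, 10), c(-0.2, 1)), "non-negative")
  # an implausible cohort (soft tissue below adipose) cannot give a curve
  bad <- data.frame(class = tissue_class_names(),
                    mean_hu = c(-1000, 50, 20, 219, 1000),
                    sd_between = 0, se_mean = 0, n_patients = 1)
  class(bad) <- c("cohort_stats", "data.frame")
  expect_error(derive_optimized_curve(bad), "implausible|increasing")
})
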