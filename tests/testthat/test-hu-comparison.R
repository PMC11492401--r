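make_vol <- function(values, shape = c(2, 1, 1)) volume3d(array(values, shape))

test_that("difference maps are signed CT - sCT and antisymmetric", {
  ct <- make_vol(c(37, -96))
  sct <- make_vol(c(0, -75))
  d <- difference_map(ct, sct)
  expect_equal(as.numeric(d$values), c(37, -21))
  expect_equal(difference_map(sct, ct)$values, -d$values)
  expect_true(all(difference_map(ct, ct)$values == 0))

  other <- volume3d(array(0, c(3, 1, 1)))
  expect_error(difference_map(ct, other), "shape")
  shifted <- volume3d(array(0, c(2, 1, 1)), origin = c(5, 0, 0))
  expect_error(difference_map(ct, shifted), "origin")
})

test_that("mae matches hand arithmetic, symmetry, and a brute-force oracle", {
  a <- make_vol(c(10, 0))
  b <- make_vol(c(0, 30))
  expect_equal(mae(a, b), 20)
  expect_equal(mae(a, a), 0)
  expect_equal(mae(a, b), mae(b, a))
  expect_error(mae(a, b, array(FALSE, c(2, 1, 1))), "empty mask")

  set.seed(12)
  x <- volume3d(array(rnorm(8000, 0, 300), c(20, 20, 20)))
  y <- volume3d(array(rnorm(8000, 0, 300), c(20, 20, 20)))
  msk <- array(runif(8000) < 0.4, c(20, 20, 20))
  # explicit sum-loop oracle
  oracle <- function(u, v, m) {
    tot <- 0; n <- 0
    for (i in which(m)) { tot <- tot + abs(u$values[i] - v$values[i]); n <- n + 1 }
    tot / n
  }
  expect_equal(mae(x, y, msk), oracle(x, y, msk), tolerance = 1e-12)
  expect_equal(mae(x, y), oracle(x, y, array(TRUE, c(20, 20, 20))), tolerance = 1e-12)
})

test_that("total MAE is the voxel-weighted average of per-region MAEs", {
  set.seed(3)
  x <- volume3d(array(rnorm(4000), c(20, 20, 10)))
  y <- volume3d(array(rnorm(4000), c(20, 20, 10)))
  part <- array(sample(1:3, 4000, replace = TRUE), c(20, 20, 10))
  pieces <- sapply(1:3, function(k) {
    m <- part == k
    c(mae(x, y, m), sum(m))
  })
  expect_equal(mae(x, y), sum(pieces[1, ] * pieces[2, ]) / sum(pieces[2, ]))
})

test_that("class overrides rewrite only the requested masks", {
  p <- generate_pair(coarse_spec(), zero_noise_classes())
  sm <- segment_classes(p$sct, threshold_scheme(opening_radius = 0))
  mod <- override_classes(p$sct, sm, c(adipose = -96, soft_tissue = 37))
  expect_identical(unique(mod$values[sm$masks$adipose]), -96)
  expect_identical(unique(mod$values[sm$masks$soft_tissue]), 37)
  expect_identical(mod$values[sm$masks$outer_bone], p$sct$values[sm$masks$outer_bone])
  # input untouched; empty override is the identity
  expect_identical(unique(p$sct$values[sm$masks$adipose]), -75)
  same <- override_classes(p$sct, sm, stats::setNames(numeric(0), character(0)))
  expect_identical(same$values, p$sct$values)
  # zero-noise phantom: overriding to the CT means zeroes the class MAE
  expect_equal(mae(p$ct, mod, sm$masks$soft_tissue), 0)
})

test_that("override to the true mean leaves the half-normal residual", {
  # after overriding a class to its CT mean, per-voxel |difference| is
  # |N(0, sd)|, whose expectation is sd * sqrt(2/pi)
  p <- generate_pair(phantom_spec(seed = 21,
                                  artifacts = list(gas_mismatch = FALSE,
                                                   fiducials = FALSE,
                                                   bone_shift_mm = 0)))
  sm <- segment_classes(p$sct, threshold_scheme(opening_radius = 0))
  mod <- override_classes(p$sct, sm, c(adipose = -96, soft_tissue = 37))
  for (cl in c("adipose", "soft_tissue")) {
    sdev <- tissue_classes()$ct_std_hu[tissue_classes()$name == cl]
    n <- sum(sm$masks[[cl]])
    expected <- sdev * sqrt(2 / pi)
    se <- sdev * sqrt(1 - 2 / pi) / sqrt(n)
    expect_lt(abs(mae(p$ct, mod, sm$masks[[cl]]) - expected), 3 * se)
  }
})

test_that("the cohort MAE table shows the override reduction for every patient", {
  co <- generate_cohort(4, coarse_spec(seed = 1,
                                       artifacts = list(gas_mismatch = TRUE,
                                                        fiducials = TRUE,
                                                        bone_shift_mm = 0)),
                        jitter = 0.1, seed = 2)
  tab <- cohort_mae_table(co, c(adipose = -96, soft_tissue = 37))
  expect_equal(nrow(tab), 4L)
  expect_true(all(tab$total_modified < tab$total_original))
  expect_true(all(tab$soft_tissue_modified < tab$soft_tissue_original))
  expect_true(all(tab$total_bone_original >= 0))
  s <- attr(tab, "summary")
  expect_true(all(c("mean", "sd") %in% names(s)))

  one <- cohort_mae_table(co[1], c(adipose = -96, soft_tissue = 37))
  s1 <- attr(one, "summary")
  expect_equal(s1$mean[s1$metric == "total_original"], one$total_original)
  expect_equal(s1$sd, rep(0, nrow(s1)))
})

test_that("metal HU suppression touches only supra-threshold voxels", {
  ct <- make_vol(c(1500, 900, -96), c(3, 1, 1))
  out <- override_metal_hu(ct, threshold_hu = 1200, replacement_hu = 37)
  expect_equal(as.numeric(out$values), c(37, 900, -96))
})
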