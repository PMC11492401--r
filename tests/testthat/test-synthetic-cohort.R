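test_that("noise-free CT carries exact class means and sCT exact bulk values", {
  p <- generate_pair(coarse_spec(), zero_noise_classes())
  m <- p$structures$masks
  expect_identical(unique(p$ct$values[m$adipose]), -96)
  expect_identical(unique(p$ct$values[m$soft_tissue]), 37)
  expect_identical(unique(p$ct$values[m$air]), -1000)
  expect_identical(unique(p$sct$values[m$soft_tissue]), 0)
  expect_setequal(unique(as.numeric(p$sct$values)), c(-1000, -75, 0, 204, 1170))
})

test_that("generated pairs are co-registered and deterministic from the seed", {
  p1 <- generate_pair(coarse_spec(seed = 42))
  p2 <- generate_pair(coarse_spec(seed = 42))
  p3 <- generate_pair(coarse_spec(seed = 43))
  expect_true(check_coregistered(p1$ct, p1$sct))
  expect_identical(p1$ct$values, p2$ct$values)
  expect_identical(p1$sct$values, p2$sct$values)
  expect_false(identical(p1$ct$values, p3$ct$values))
})

test_that("class masks partition the grid and organs stay inside the body", {
  p <- generate_pair(coarse_spec())
  m <- p$structures$masks
  cls_sum <- m$air + m$adipose + m$soft_tissue + m$inner_bone + m$outer_bone
  expect_true(all(cls_sum == 1L))
  for (organ in c("ptv", "bladder", "rectum", "femoral_heads"))
    expect_true(all(m$body[m[[organ]]]))
  expect_false(any(m$ptv & (m$inner_bone | m$outer_bone)))
})

test_that("empirical class noise converges to the configured sd", {
  p <- generate_pair(phantom_spec(seed = 7,
                                  artifacts = list(gas_mismatch = FALSE,
                                                   fiducials = FALSE,
                                                   bone_shift_mm = 0)))
  m <- p$structures$masks
  for (cl in c("adipose", "soft_tissue", "outer_bone")) {
    v <- p$ct$values[m[[cl]]]
    target <- tissue_classes()$ct_std_hu[tissue_classes()$name == cl]
    se <- target / sqrt(2 * length(v))  # se of a sample sd
    expect_lt(abs(sd(v) - target), 3 * se)
    se_mean <- target / sqrt(length(v))
    expect_lt(abs(mean(v) - tissue_classes()$ct_mean_hu[tissue_classes()$name == cl]),
              3 * se_mean)
  }
})

test_that("geometry that does not fit the grid errors naming the element", {
  expect_error(phantom_spec(body_semiaxes = c(300, 65)), "body semi-axes")
  expect_error(
    generate_pair(phantom_spec(ptv = list(center = c(0, -45, -12), radius = 30))),
    "PTV")
})

test_that("artifact switches behave independently and identity holds when off", {
  spec_off <- coarse_spec(seed = 5)
  base <- generate_pair(spec_off)
  off <- inject_artifacts(base$ct, base$sct, base$structures, spec_off)
  expect_identical(off$ct$values, base$ct$values)
  expect_identical(off$sct$values, base$sct$values)

  spec_gas <- coarse_spec(seed = 5, artifacts = list(gas_mismatch = TRUE,
                                                     fiducials = FALSE,
                                                     bone_shift_mm = 0))
  gas <- inject_artifacts(base$ct, base$sct, base$structures, spec_gas)
  expect_gt(mae(gas$ct, gas$sct), mae(base$ct, base$sct))
  expect_identical(gas$sct$values, base$sct$values)  # CT-only artifact

  spec_fid <- coarse_spec(seed = 5, artifacts = list(gas_mismatch = FALSE,
                                                     fiducials = TRUE,
                                                     bone_shift_mm = 0))
  fid <- inject_artifacts(base$ct, base$sct, base$structures, spec_fid)
  expect_identical(fid$sct$values, base$sct$values)  # absent from sCT
  expect_gte(max(fid$ct$values[base$structures$masks$ptv]), 1000)

  spec_shift <- coarse_spec(seed = 5, artifacts = list(gas_mismatch = FALSE,
                                                       fiducials = FALSE,
                                                       bone_shift_mm = 16))
  sh <- inject_artifacts(base$ct, base$sct, base$structures, spec_shift)
  expect_identical(sh$ct$values, base$ct$values)    # sCT-only artifact
  expect_false(identical(sh$sct$values, base$sct$values))
  # vacated cortical voxels now carry the soft-tissue bulk value
  vac <- base$structures$masks$femoral_head_right &
    !sh$structures$masks$femoral_head_right_sct
  expect_true(all(sh$sct$values[vac] == 0))

  spec_far <- coarse_spec(seed = 5, artifacts = list(gas_mismatch = FALSE,
                                                     fiducials = FALSE,
                                                     bone_shift_mm = 120))
  expect_error(inject_artifacts(base$ct, base$sct, base$structures, spec_far),
               "outside")
})

test_that("cohorts are reproducible, sized, and degenerate to generate_pair", {
  expect_error(generate_cohort(0), "count")
  co1 <- generate_cohort(3, coarse_spec(), jitter = 0.1, seed = 11)
  co2 <- generate_cohort(3, coarse_spec(), jitter = 0.1, seed = 11)
  expect_length(co1, 3L)
  expect_identical(lapply(co1, `[[`, "ct"), lapply(co2, `[[`, "ct"))
  for (p in co1) expect_true(check_coregistered(p$ct, p$sct))

  # n = 1, zero jitter, artifacts off: equals a plain generate_pair at the
  # patient seed (seed + 1 by the counter scheme)
  co <- generate_cohort(1, coarse_spec(), jitter = 0, seed = 20)
  ref <- generate_pair(coarse_spec(seed = 21L))
  expect_identical(co[[1]]$ct$values, ref$ct$values)
  expect_identical(co[[1]]$sct$values, ref$sct$values)
})

test_that("volumes and structure sets survive NIfTI round trips", {
  p <- generate_pair(coarse_spec(seed = 2))
  tf <- tempfile(fileext = ".nii.gz")
  write_volume(p$ct, tf)
  back <- read_volume(tf)
  expect_equal(back$spacing, p$ct$spacing)
  expect_equal(back$origin, p$ct$origin)
  expect_equal(back$values, p$ct$values, tolerance = 1e-5) # float32 storage
  prefix <- tempfile()
  write_structures(p$structures, prefix)
  ss <- read_structures(prefix)
  for (nm in names(p$structures$masks))
    expect_identical(ss$masks[[nm]], p$structures$masks[[nm]])
})
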