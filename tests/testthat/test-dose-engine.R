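test_that("radiological path length is exact on water and hand cases", {
  water <- volume3d(array(1, c(10, 10, 10)), spacing = c(2, 2, 2))
  expect_equal(radiological_path_length(water, c(-9, 0, 0), c(9, 0, 0)), 18,
               tolerance = 1e-9)
  # axis-aligned ray through two 2 mm voxels of RED 0.95 and 1.7
  two <- volume3d(array(c(0.95, 1.7), c(2, 1, 1)), spacing = c(2, 2, 2))
  expect_equal(radiological_path_length(two, c(-2, 0, 0), c(2, 0, 0)),
               2 * 0.95 + 2 * 1.7, tolerance = 1e-12)
  # degenerate segment
  expect_identical(radiological_path_length(water, c(1, 1, 1), c(1, 1, 1)), 0)
  # fully outside the grid
  expect_identical(radiological_path_length(water, c(50, 50, 50), c(60, 50, 50)), 0)
})

test_that("traversal lengths conserve the in-grid chord length", {
  ones <- volume3d(array(1, c(17, 23, 9)), spacing = c(1.7, 2.3, 3.1))
  set.seed(5)
  for (i in 1:50) {
    p0 <- runif(3, -60, 60)
    p1 <- runif(3, -60, 60)
    expect_equal(radiological_path_length(ones, p0, p1),
                 chord_in_grid_length(ones, p0, p1), tolerance = 1e-9)
  }
})

test_that("Siddon agrees with a dense-sampling oracle on random chords", {
  set.seed(6)
  v <- volume3d(array(runif(4096, 0, 2), c(16, 16, 16)), spacing = c(2.5, 2.5, 2.5))
  for (i in 1:20) {
    p0 <- runif(3, -30, 30)
    p1 <- runif(3, -30, 30)
    got <- radiological_path_length(v, p0, p1)
    ref <- rpl_supersample_oracle(v, p0, p1)
    if (ref > 1) expect_lt(abs(got - ref) / ref, 0.005)
  }
})

uniform_red <- function(red = 1, shape = c(21, 21, 21), spacing = c(2, 2, 2)) {
  volume3d(array(red, shape), spacing = spacing)
}

test_that("dose follows closed-form attenuation after inverse-square correction", {
  red <- uniform_red(1)
  body <- array(TRUE, dim(red$values))
  mu <- 0.005
  plan <- dose_plan(list(beam_spec(c(-500, 0, 0), c(0, 0, 0), aperture = 30,
                                   mu = mu, dref = 500)), "arc", 40)
  dose <- compute_dose(plan, red, body)
  # two on-axis voxels separated by depth delta
  d1 <- dose$values[11, 11, 11]           # at (0,0,0), depth 500 from source
  d2 <- dose$values[16, 11, 11]           # at (10,0,0)
  delta <- 10
  invsq1 <- (500 / 500)^2
  invsq2 <- (500 / 510)^2
  expect_equal((d2 / invsq2) / (d1 / invsq1), exp(-mu * delta), tolerance = 1e-9)
})

test_that("dose is linear in beam weights and shaped only by geometry in vacuum", {
  red <- uniform_red(0.8, shape = c(15, 15, 15))
  body <- array(TRUE, dim(red$values))
  b <- beam_spec(c(0, -400, 0), c(0, 0, 0), aperture = 25, dref = 400)
  plan1 <- dose_plan(list(b), "arc", 40)
  b2 <- b; b2$weight <- 2
  plan2 <- dose_plan(list(b2), "arc", 40)
  d1 <- compute_dose(plan1, red, body)
  d2 <- compute_dose(plan2, red, body)
  expect_equal(d2$values, 2 * d1$values, tolerance = 1e-12)

  vac <- uniform_red(0, shape = c(15, 15, 15))
  dv <- compute_dose(plan1, vac, body)
  # on the central axis, vacuum dose is pure inverse square
  expect_equal(dv$values[8, 8, 8] / dv$values[8, 1, 8],
               ((400 - 14) / 400)^2, tolerance = 1e-9)
  expect_error(compute_dose(dose_plan(list(beam_spec(c(0, -400, 0), c(0, 0, 0),
                                                     25, weight = 0)), "arc", 40),
                            red, body), "zero")
})

test_that("dose is invariant under beam relabeling and bit-stable on reruns", {
  p <- generate_pair(coarse_spec(seed = 9))
  cur <- build_original_curve()
  red <- predict(cur, p$sct)
  body <- p$structures$masks$body
  plan <- make_plan("robotic", p$structures$masks$ptv, red, body,
                    n_beams = 12, seed = 3)
  d1 <- compute_dose(plan, red, body)
  d2 <- compute_dose(plan, red, body)
  expect_identical(d1$values, d2$values)
  perm <- plan
  perm$beams <- rev(plan$beams)
  d3 <- compute_dose(perm, red, body)
  expect_equal(d3$values, d1$values, tolerance = 1e-12)
})

test_that("raising density along the path can only reduce distal dose", {
  red <- uniform_red(1, shape = c(21, 21, 21))
  body <- array(TRUE, dim(red$values))
  plan <- dose_plan(list(beam_spec(c(-500, 0, 0), c(0, 0, 0), 30, dref = 500)),
                    "arc", 40)
  base <- compute_dose(plan, red, body)
  denser <- red
  denser$values[5, 11, 11] <- 2  # proximal voxel on the axis
  mod <- compute_dose(plan, denser, body)
  distal <- base$values[12:21, 11, 11]
  expect_true(all(mod$values[12:21, 11, 11] < distal))
  # proximal voxels are unaffected
  expect_equal(mod$values[1:4, 11, 11], base$values[1:4, 11, 11])
})

test_that("plans are constructed, normalized and serialized faithfully", {
  p <- generate_pair(coarse_spec(seed = 10))
  red <- predict(build_original_curve(), p$sct)
  body <- p$structures$masks$body
  ptv <- p$structures$masks$ptv

  arc <- make_plan("arc", ptv, red, body, n_beams = 36, seed = 1)
  expect_length(arc$beams, 36L)
  src_z <- vapply(arc$beams, function(b) b$source[3], 0)
  expect_equal(diff(range(src_z)), 0)  # coplanar
  d95 <- dvh_metric(compute_dvh(compute_dose(arc, red, body), ptv), 95)
  expect_lt(abs(d95 - arc$prescription) / arc$prescription, 0.001)

  r1 <- make_plan("robotic", ptv, red, body, n_beams = 10, seed = 77)
  r2 <- make_plan("robotic", ptv, red, body, n_beams = 10, seed = 77)
  expect_equal(r1$beams, r2$beams)
  # robotic beams come from the superior hemisphere (sources above targets)
  expect_true(all(vapply(r1$beams, function(b) b$source[3] > b$aim[3], TRUE)))

  tf <- tempfile(fileext = ".yaml")
  write_plan(r1, tf)
  back <- read_plan(tf)
  db1 <- compute_dose(r1, red, body)
  db2 <- compute_dose(back, red, body)
  expect_equal(db2$values, db1$values, tolerance = 1e-12)

  expect_error(make_plan("arc", array(FALSE, dim(red$values)), red, body), "empty")
})
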