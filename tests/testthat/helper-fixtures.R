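# Shared fixtures. Unit tests mostly use a coarse grid with the same
# 192x192x144 mm field of view as the default phantom (48x48x24 voxels at
# 4x4x6 mm), so the anatomy is unchanged but everything runs fast.

coarse_spec <- function(seed = 1L, artifacts = list(gas_mismatch = FALSE,
                                                    fiducials = FALSE,
                                                    bone_shift_mm = 0)) {
  phantom_spec(shape = c(48L, 48L, 24L), spacing = c(4, 4, 6),
               artifacts = artifacts, seed = seed)
}

zero_noise_classes <- function() tissue_classes(ct_std_hu = rep(0, 5))

# memoised default-condition cohort (10 patients, default grid and
# artifacts, Gaussian CT noise) shared by the acceptance tests
.fixture_env <- new.env(parent = emptyenv())

default_noisy_cohort <- function(seed = 1L) {
  key <- paste0("cohort", seed)
  if (is.null(.fixture_env[[key]]))
    .fixture_env[[key]] <- generate_cohort(10, phantom_spec(), jitter = 0.1,
                                           seed = seed)
  .fixture_env[[key]]
}

# clip a segment to the grid's bounding box and return the inside length;
# independent oracle for Siddon length conservation
chord_in_grid_length <- function(vol, p0, p1) {
  lo <- vol$origin - vol$spacing / 2
  hi <- lo + dim(vol$values) * vol$spacing
  d <- p1 - p0
  t0 <- 0; t1 <- 1
  for (a in 1:3) {
    if (d[a] == 0) {
      if (p0[a] <= lo[a] || p0[a] >= hi[a]) return(0)
    } else {
      ta <- (lo[a] - p0[a]) / d[a]; tb <- (hi[a] - p0[a]) / d[a]
      t0 <- max(t0, min(ta, tb)); t1 <- min(t1, max(ta, tb))
    }
  }
  if (t0 >= t1) return(0)
  (t1 - t0) * sqrt(sum(d^2))
}

# dense-sampling numeric oracle for the radiological path length
rpl_supersample_oracle <- function(vol, p0, p1, step = 0.02) {
  L <- sqrt(sum((p1 - p0)^2))
  if (L == 0) return(0)
  n <- max(2L, ceiling(L / step))
  t <- (seq_len(n) - 0.5) / n
  shp <- dim(vol$values)
  acc <- 0
  idx <- matrix(0L, n, 3)
  for (a in 1:3) {
    x <- p0[a] + t * (p1[a] - p0[a])
    idx[, a] <- as.integer(floor((x - (vol$origin[a] - vol$spacing[a] / 2)) /
                                   vol$spacing[a])) + 1L
  }
  ok <- idx[, 1] >= 1 & idx[, 1] <= shp[1] & idx[, 2] >= 1 & idx[, 2] <= shp[2] &
        idx[, 3] >= 1 & idx[, 3] <= shp[3]
  if (!any(ok)) return(0)
  vals <- vol$values[idx[ok, , drop = FALSE]]
  sum(vals) * L / n
}

# exhaustive gamma oracle: for every reference voxel above the cutoff,
# minimise over ALL sample points of the search grid (no early exit),
# interpolating the evaluated dose trilinearly - independent of the
# bounded-search implementation
gamma_brute_oracle <- function(reference, evaluated, criteria, prescription) {
  shp <- dim(reference$values)
  sp <- reference$spacing; org <- reference$origin
  m <- floor(criteria$search_radius_mm / criteria$step_mm + 1e-9)
  offs <- expand.grid(dx = -m:m, dy = -m:m, dz = -m:m) * criteria$step_mm
  offs <- offs[rowSums(offs^2) <= criteria$search_radius_mm^2 + 1e-12, ]
  off_r2 <- rowSums(offs^2)

  # trilinear interpolation of the evaluated dose at many points at once
  interp_many <- function(px, py, pz) {
    f1 <- (px - org[1]) / sp[1]
    f2 <- (py - org[2]) / sp[2]
    f3 <- (pz - org[3]) / sp[3]
    ok <- f1 >= 0 & f1 <= shp[1] - 1 & f2 >= 0 & f2 <= shp[2] - 1 &
          f3 >= 0 & f3 <= shp[3] - 1
    out <- rep(NA_real_, length(px))
    if (!any(ok)) return(out)
    i1 <- pmin(pmax(floor(f1[ok]), 0), shp[1] - 2)
    i2 <- pmin(pmax(floor(f2[ok]), 0), shp[2] - 2)
    i3 <- pmin(pmax(floor(f3[ok]), 0), shp[3] - 2)
    w1 <- f1[ok] - i1; w2 <- f2[ok] - i2; w3 <- f3[ok] - i3
    acc <- 0
    for (dz in 0:1) for (dy in 0:1) for (dx in 0:1) {
      wt <- (if (dx) w1 else 1 - w1) * (if (dy) w2 else 1 - w2) *
            (if (dz) w3 else 1 - w3)
      acc <- acc + wt * evaluated$values[cbind(i1 + dx + 1, i2 + dy + 1,
                                               i3 + dz + 1)]
    }
    out[ok] <- acc
    out
  }

  gam <- array(NA_real_, shp)
  cutoff <- criteria$cutoff * prescription
  for (k in seq_len(shp[3])) for (j in seq_len(shp[2])) for (i in seq_len(shp[1])) {
    dr <- reference$values[i, j, k]
    if (!(dr > 0) || dr < cutoff) next
    px <- org[1] + (i - 1) * sp[1]
    py <- org[2] + (j - 1) * sp[2]
    pz <- org[3] + (k - 1) * sp[3]
    denom <- criteria$dose_tol * if (criteria$norm == "local") dr else prescription
    ev <- interp_many(px + offs$dx, py + offs$dy, pz + offs$dz)
    g2 <- ((ev - dr) / denom)^2 + off_r2 / criteria$dta_mm^2
    gam[i, j, k] <- sqrt(min(g2, na.rm = TRUE))
  }
  gam
}
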