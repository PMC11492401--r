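#' Structure set: named masks on a common grid
#'
#' A collection of logical voxel masks (body, organs and per-tissue-class
#' masks) sharing one grid. The five class masks exactly partition the grid
#' at generation time; organ masks are subsets of the body.
#'
#' @param masks named list of logical 3D arrays, all the same shape.
#' @param spacing,origin grid metadata (see [volume3d()]).
#' @return An object of class `structure_set`.
#' @export
structure_set <- function(masks, spacing, origin) {
  if (!length(masks) || is.null(names(masks)) || any(names(masks) == ""))
    stopf("`masks` must be a non-empty named list")
  shp <- dim(masks[[1]])
  for (nm in names(masks)) {
    m <- masks[[nm]]
    if (!is.logical(m) || !identical(dim(m), shp))
      stopf("mask '%s' must be a logical array of shape %s", nm,
            paste(shp, collapse = "x"))
  }
  structure(list(masks = masks, spacing = as.numeric(spacing),
                 origin = as.numeric(origin)),
            class = "structure_set")
}

#' @export
print.structure_set <- function(x, ...) {
  cat(sprintf("<structure_set> %s voxels\n",
              paste(dim(x$masks[[1]]), collapse = "x")))
  for (nm in names(x$masks))
    cat(sprintf("  %-22s %d voxels\n", nm, sum(x$masks[[nm]])))
  invisible(x)
}

ss_shape <- function(ss) dim(ss$masks[[1]])

#' Digital pelvis phantom specification
#'
#' Describes the geometry of one synthetic pelvis: an elliptic-cylinder body
#' with a subcutaneous adipose shell, a pelvic-ring torus and two femoral-head
#' spheres (each with a cortical outer-bone shell around a trabecular
#' inner-bone core), and spherical/cylindrical organs (PTV, bladder, rectum).
#' All lengths in mm; the grid is centred on the world origin.
#'
#' The default grid is 96x96x48 voxels at 2x2x3 mm (a 192x192x144 mm field of
#' view); finer clinical-resolution grids are supported by overriding `shape`
#' and `spacing`.
#'
#' `artifacts` holds three independent switches for the discrepancy types a
#' clinical sCT exhibits against same-day CT: `gas_mismatch` (an air pocket in
#' the rectum present on CT only), `fiducials` (small high-HU markers in the
#' PTV on CT only — gold seeds are invisible on MRI and therefore absent from
#' sCT), and `bone_shift_mm` (rigid medial translation of the right femoral
#' head in the sCT only, emulating atlas bone mislabeling).
#'
#' @param shape integer length-3 grid size.
#' @param spacing numeric length-3 voxel size in mm.
#' @param body_semiaxes ellipse semi-axes (x, y) of the body in mm.
#' @param adipose_thickness subcutaneous fat shell thickness in mm.
#' @param femoral list: `offset` (centre of the right head; left is mirrored
#'   in x), `radius`, `cortex` (cortical shell thickness).
#' @param pelvic_ring list: torus `center`, `major` and `minor` radii,
#'   `cortex` thickness.
#' @param ptv,bladder lists with `center` and `radius` (spheres).
#' @param rectum list with `center_xy`, `radius`, `z_range` (z-axis cylinder).
#' @param artifacts list of switches, see Details.
#' @param seed integer RNG seed controlling this phantom's noise and
#'   artifact draws.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(96L, 96L, 48L),
                         spacing = c(2, 2, 3),
                         body_semiaxes = c(85, 65),
                         adipose_thickness = 12,
                         femoral = list(offset = c(44, 0, -6), radius = 18, cortex = 4),
                         pelvic_ring = list(center = c(0, 0, 6), major = 36,
                                            minor = 8, cortex = 3),
                         ptv = list(center = c(0, -20, -12), radius = 12),
                         bladder = list(center = c(0, 12, 0), radius = 18),
                         rectum = list(center_xy = c(0, -40), radius = 7.5,
                                       z_range = c(-27, 15)),
                         artifacts = list(gas_mismatch = TRUE, fiducials = TRUE,
                                          bone_shift_mm = 0),
                         seed = 1L) {
  spec <- list(shape = as.integer(shape), spacing = as.numeric(spacing),
               body_semiaxes = as.numeric(body_semiaxes),
               adipose_thickness = as.numeric(adipose_thickness),
               femoral = femoral, pelvic_ring = pelvic_ring,
               ptv = ptv, bladder = bladder, rectum = rectum,
               artifacts = artifacts, seed = as.integer(seed))
  arts <- list(gas_mismatch = FALSE, fiducials = FALSE, bone_shift_mm = 0,
               gas_radius_mm = 6, n_fiducials = 3L, fiducial_hu = 1500,
               fiducial_radius_mm = 2)
  arts[names(artifacts)] <- artifacts
  spec$artifacts <- arts
  class(spec) <- "phantom_spec"
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(spec) {
  half <- (spec$shape - 1) / 2 * spec$spacing
  if (spec$body_semiaxes[1] > half[1] || spec$body_semiaxes[2] > half[2])
    stopf("phantom geometry exceeds grid: body semi-axes (%g, %g) mm do not fit a grid of half-extent (%g, %g) mm",
          spec$body_semiaxes[1], spec$body_semiaxes[2], half[1], half[2])
  if (spec$adipose_thickness >= min(spec$body_semiaxes))
    stopf("phantom geometry invalid: adipose shell thicker than body")
  invisible(spec)
}

# world coordinate arrays for a spec's grid
grid_coords <- function(shape, spacing) {
  origin <- -(shape - 1) / 2 * spacing
  list(x = origin[1] + (seq_len(shape[1]) - 1) * spacing[1],
       y = origin[2] + (seq_len(shape[2]) - 1) * spacing[2],
       z = origin[3] + (seq_len(shape[3]) - 1) * spacing[3],
       origin = origin)
}

sphere_mask <- function(g, shape, center, radius) {
  dx2 <- (g$x - center[1])^2
  dy2 <- (g$y - center[2])^2
  dz2 <- (g$z - center[3])^2
  array(outer(outer(dx2, dy2, `+`), dz2, `+`) <= radius^2, dim = shape)
}

# build the class label array (1=air..5=outer_bone) and all masks
build_phantom_masks <- function(spec) {
  shp <- spec$shape
  g <- grid_coords(shp, spec$spacing)

  ax <- spec$body_semiaxes[1]; ay <- spec$body_semiaxes[2]
  exy <- outer((g$x / ax)^2, (g$y / ay)^2, `+`)         # nx x ny
  body2d <- exy <= 1
  t <- spec$adipose_thickness
  inner2d <- outer((g$x / (ax - t))^2, (g$y / (ay - t))^2, `+`) <= 1
  body <- array(rep(body2d, shp[3]), dim = shp)
  inner <- array(rep(inner2d, shp[3]), dim = shp)

  lab <- array(1L, dim = shp)              # air
  lab[body] <- 2L                          # adipose shell ...
  lab[inner] <- 3L                         # ... soft-tissue interior

  # pelvic ring torus (in the x-y plane)
  pr <- spec$pelvic_ring
  rxy <- sqrt(outer((g$x - pr$center[1])^2, (g$y - pr$center[2])^2, `+`))
  ring2 <- outer((rxy - pr$major)^2, (g$z - pr$center[3])^2, `+`)
  dim(ring2) <- shp
  torus_outer <- ring2 <= pr$minor^2
  torus_core <- ring2 <= (pr$minor - pr$cortex)^2
  # femoral heads (right at +x, left mirrored)
  fo <- spec$femoral$offset; fr <- spec$femoral$radius; fc <- spec$femoral$cortex
  fh_r <- sphere_mask(g, shp, fo, fr)
  fh_l <- sphere_mask(g, shp, c(-fo[1], fo[2], fo[3]), fr)
  fh_r_core <- sphere_mask(g, shp, fo, fr - fc)
  fh_l_core <- sphere_mask(g, shp, c(-fo[1], fo[2], fo[3]), fr - fc)

  bone <- torus_outer | fh_r | fh_l
  if (any(bone & !inner))
    stopf("phantom geometry invalid: bone (pelvic ring or femoral head) extends outside the inner soft-tissue region")
  lab[bone] <- 5L
  lab[torus_core | fh_r_core | fh_l_core] <- 4L
  # cortical shell of the femoral heads takes precedence over the ring core
  lab[(fh_r & !fh_r_core) | (fh_l & !fh_l_core)] <- 5L

  ptv <- sphere_mask(g, shp, spec$ptv$center, spec$ptv$radius)
  bladder <- sphere_mask(g, shp, spec$bladder$center, spec$bladder$radius)
  rc <- spec$rectum
  rect2d <- outer((g$x - rc$center_xy[1])^2, (g$y - rc$center_xy[2])^2, `+`) <= rc$radius^2
  rectz <- g$z >= rc$z_range[1] & g$z <= rc$z_range[2]
  rectum <- array(outer(rect2d, rectz, `&`), dim = shp)

  if (any(ptv & !body)) stopf("phantom geometry invalid: PTV extends outside body")
  if (any(bladder & !body)) stopf("phantom geometry invalid: bladder extends outside body")
  if (any(rectum & !body)) stopf("phantom geometry invalid: rectum extends outside body")
  if (any(ptv & lab >= 4L)) stopf("phantom geometry invalid: PTV intersects bone")
  # bladder and rectum are soft-tissue organs; where their analytic shapes
  # graze bone or the fat shell, keep only the soft-tissue voxels
  bladder <- bladder & lab == 3L
  rectum <- rectum & lab == 3L

  masks <- list(body = body,
                ptv = ptv, bladder = bladder, rectum = rectum,
                femoral_heads = fh_r | fh_l,
                femoral_head_right = fh_r, femoral_head_left = fh_l,
                air = lab == 1L, adipose = lab == 2L, soft_tissue = lab == 3L,
                inner_bone = lab == 4L, outer_bone = lab == 5L)
  list(labels = lab,
       structures = structure_set(masks, spec$spacing, g$origin))
}

#' Generate one co-registered CT/sCT phantom pair
#'
#' Builds the phantom's tissue label map, then draws the CT as per-voxel
#' independent Gaussians (class CT mean and standard deviation) and the sCT
#' as the exact per-class bulk HU (piecewise constant). No artifacts are
#' applied here; see [inject_artifacts()]. The same `spec` (including its
#' `seed`) always yields bit-identical output.
#'
#' @param spec a [phantom_spec()].
#' @param classes a tissue class scheme, see [tissue_classes()].
#' @return A list with elements `ct` and `sct` ([volume3d()]s) and
#'   `structures` (a [structure_set()] whose five class masks partition the
#'   grid).
#' @export
generate_pair <- function(spec = phantom_spec(), classes = tissue_classes()) {
  cls <- classes_ordered(classes)
  pm <- build_phantom_masks(spec)
  lab <- pm$labels
  mu <- cls$ct_mean_hu[lab]
  sd <- cls$ct_std_hu[lab]
  noise <- with_seed(spec$seed, stats::rnorm(length(lab)))
  ct_vals <- array(mu + sd * noise, dim = dim(lab))
  sct_vals <- array(cls$sct_bulk_hu[lab], dim = dim(lab))
  origin <- pm$structures$origin
  list(ct = volume3d(ct_vals, spec$spacing, origin),
       sct = volume3d(sct_vals, spec$spacing, origin),
       structures = pm$structures)
}

#' Inject CT/sCT discrepancy artifacts
#'
#' Applies up to three independent artifact types to a co-registered pair:
#' * `gas_mismatch`: an air-HU pocket inside the rectum, on the CT only
#'   (bowel/rectal filling differs between the two acquisitions);
#' * `fiducials`: small (<= 3 voxel radius) markers at >= 1000 HU inside the
#'   PTV, on the CT only (metal seeds produce no MRI signal and are absent
#'   from sCT);
#' * `bone_shift_mm`: the right femoral head rigidly translated medially in
#'   the sCT only (atlas mislabeling); vacated voxels are filled with the
#'   soft-tissue bulk HU. The translated sCT head is returned as an extra
#'   mask `femoral_head_right_sct`.
#'
#' @param ct,sct co-registered [volume3d()] volumes.
#' @param structs the pair's [structure_set()].
#' @param spec the [phantom_spec()] whose `artifacts` switches apply.
#' @param seed RNG seed for artifact placement (default: the spec seed).
#' @param classes tissue class scheme (for bulk/air HU values).
#' @return A list `(ct, sct, structures)`; inputs are not mutated. With all
#'   switches off the volumes are returned unchanged.
#' @export
inject_artifacts <- function(ct, sct, structs, spec, seed = spec$seed,
                             classes = tissue_classes()) {
  check_coregistered(ct, sct, "CT and sCT")
  cls <- classes_ordered(classes)
  arts <- spec$artifacts
  shp <- dim(ct$values)
  g <- grid_coords(shp, ct$spacing)
  ct_vals <- ct$values
  sct_vals <- sct$values
  masks <- structs$masks

  with_seed(seed, {
    if (isTRUE(arts$gas_mismatch)) {
      rect_idx <- which(masks$rectum, arr.ind = TRUE)
      ctr_row <- rect_idx[sample.int(nrow(rect_idx), 1L), ]
      center <- c(g$x[ctr_row[1]], g$y[ctr_row[2]], g$z[ctr_row[3]])
      pocket <- sphere_mask(g, shp, center, arts$gas_radius_mm) & masks$rectum
      ct_vals[pocket] <- cls$ct_mean_hu[cls$name == "air"]
    }
    if (isTRUE(arts$fiducials)) {
      ptv_idx <- which(masks$ptv, arr.ind = TRUE)
      rows <- ptv_idx[sample.int(nrow(ptv_idx), arts$n_fiducials), , drop = FALSE]
      for (r in seq_len(nrow(rows))) {
        center <- c(g$x[rows[r, 1]], g$y[rows[r, 2]], g$z[rows[r, 3]])
        marker <- sphere_mask(g, shp, center, arts$fiducial_radius_mm)
        ct_vals[marker] <- arts$fiducial_hu
      }
    }
  })

  if (isTRUE(arts$bone_shift_mm > 0)) {
    shift_vox <- round(c(-arts$bone_shift_mm, 0, 0) / ct$spacing)
    src <- which(masks$femoral_head_right, arr.ind = TRUE)
    dst <- sweep(src, 2, as.integer(shift_vox), `+`)
    if (any(dst < 1L) || any(dst[, 1] > shp[1]) || any(dst[, 2] > shp[2]) ||
        any(dst[, 3] > shp[3]))
      stopf("bone shift moves femoral head outside the grid")
    if (!all(masks$body[dst]))
      stopf("bone shift moves femoral head outside the body")
    vals <- sct_vals[src]
    soft_bulk <- cls$sct_bulk_hu[cls$name == "soft_tissue"]
    sct_vals[src] <- soft_bulk
    sct_vals[dst] <- vals
    shifted <- array(FALSE, dim = shp)
    shifted[dst] <- TRUE
    masks$femoral_head_right_sct <- shifted
  }

  list(ct = vol_like(ct, ct_vals), sct = vol_like(sct, sct_vals),
       structures = structure_set(masks, structs$spacing, structs$origin))
}

#' Generate a seeded cohort of phantom pairs
#'
#' Produces `n` independent CT/sCT pairs with per-patient geometry jitter
#' (uniform +/-`jitter` relative perturbation of the body semi-axes and of
#' the PTV, bladder and rectum radii) and the artifact switches of
#' `base_spec`. Patient `i` uses seed `seed + i` (a documented counter
#' scheme, so extending the cohort never reshuffles existing patients) and
#' the whole cohort is bit-reproducible from `seed`.
#'
#' @param n number of patients (>= 1).
#' @param base_spec the [phantom_spec()] every patient derives from.
#' @param jitter relative geometry jitter half-width (0 disables).
#' @param seed master integer seed.
#' @param classes tissue class scheme.
#' @return A list of `n` elements, each a list with `patient`, `seed`, `ct`,
#'   `sct`, `structures` and `spec`.
#' @export
generate_cohort <- function(n, base_spec = phantom_spec(), jitter = 0.1,
                            seed = 1L, classes = tissue_classes()) {
  if (!is.numeric(n) || length(n) != 1L || n < 1)
    stopf("`n` must be a count >= 1")
  n <- as.integer(n)
  lapply(seq_len(n), function(i) {
    pseed <- as.integer(seed) + i
    spec_i <- base_spec
    if (jitter > 0) {
      f <- with_seed(pseed, stats::runif(5, 1 - jitter, 1 + jitter))
      spec_i$body_semiaxes <- spec_i$body_semiaxes * f[1:2]
      spec_i$ptv$radius <- spec_i$ptv$radius * f[3]
      spec_i$bladder$radius <- spec_i$bladder$radius * f[4]
      spec_i$rectum$radius <- spec_i$rectum$radius * f[5]
    }
    spec_i$seed <- pseed
    pair <- generate_pair(spec_i, classes)
    pair <- inject_artifacts(pair$ct, pair$sct, pair$structures, spec_i,
                             seed = pseed + 1000000L, classes = classes)
    c(list(patient = i, seed = pseed), pair, list(spec = spec_i))
  })
}

#' Write/read a structure set as NIfTI label maps plus a JSON legend
#'
#' The five tissue-class masks are written as one uint8 label map
#' (`<prefix>_classes.nii.gz`, 0 = unclassified); the remaining masks are
#' packed as bit flags into `<prefix>_organs.nii.gz`. The legend JSON maps
#' labels and bits back to names.
#'
#' @param ss a [structure_set()].
#' @param prefix output path prefix.
#' @return `write_structures` returns the legend path invisibly;
#'   `read_structures` returns a [structure_set()].
#' @export
write_structures <- function(ss, prefix) {
  cls_names <- intersect(tissue_class_names(), names(ss$masks))
  shp <- ss_shape(ss)
  lab <- array(0L, dim = shp)
  for (i in seq_along(cls_names)) lab[ss$masks[[cls_names[i]]]] <- i
  other <- setdiff(names(ss$masks), cls_names)
  bits <- array(0, dim = shp)
  for (i in seq_along(other)) bits <- bits + ss$masks[[other[i]]] * 2^(i - 1)
  write_volume(volume3d(lab + 0, ss$spacing, ss$origin),
               paste0(prefix, "_classes.nii.gz"))
  write_volume(volume3d(bits, ss$spacing, ss$origin),
               paste0(prefix, "_organs.nii.gz"))
  legend <- list(classes = as.list(stats::setNames(seq_along(cls_names), cls_names)),
                 organ_bits = as.list(stats::setNames(seq_along(other) - 1, other)))
  path <- paste0(prefix, "_legend.json")
  jsonlite::write_json(legend, path, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_structures
#' @export
read_structures <- function(prefix) {
  legend <- jsonlite::read_json(paste0(prefix, "_legend.json"))
  labv <- read_volume(paste0(prefix, "_classes.nii.gz"))
  bitv <- read_volume(paste0(prefix, "_organs.nii.gz"))
  masks <- list()
  for (nm in names(legend$classes))
    masks[[nm]] <- labv$values == legend$classes[[nm]]
  for (nm in names(legend$organ_bits))
    masks[[nm]] <- bitwAnd(as.integer(round(bitv$values)),
                           as.integer(2^legend$organ_bits[[nm]])) > 0
  for (nm in names(masks)) dim(masks[[nm]]) <- dim(labv$values)
  # restore canonical ordering: organs first, classes last (as generated)
  structure_set(masks, labv$spacing, labv$origin)
}
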