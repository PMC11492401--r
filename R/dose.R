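#' Radiological path length along a segment
#'
#' Exact Siddon voxel traversal: the sum over traversed voxels of the
#' geometric intersection length times the voxel's relative electron
#' density, i.e. the water-equivalent length of the segment. Portions of the
#' segment outside the grid contribute zero; a degenerate segment
#' (`p0 == p1`) returns 0.
#'
#' @param red a [volume3d()] of relative electron density.
#' @param p0,p1 numeric length-3 world points in mm.
#' @return Water-equivalent length in mm.
#' @examples
#' water <- volume3d(array(1, c(10, 10, 10)), spacing = c(2, 2, 2))
#' radiological_path_length(water, c(-9, 0, 0), c(9, 0, 0)) # 18 mm
#' @export
radiological_path_length <- function(red, p0, p1) {
  stopifnot(inherits(red, "volume3d"))
  p0 <- as.numeric(p0); p1 <- as.numeric(p1)
  if (length(p0) != 3L || length(p1) != 3L || any(!is.finite(c(p0, p1))))
    stopf("segment endpoints must be finite length-3 points")
  cpp_rpl(red$values, dim(red$values), red$spacing, red$origin, p0, p1)
}

#' Beam specification
#'
#' One divergent beam of the simplified dose engine: a point source, an aim
#' point defining the central axis, a circular aperture of radius
#' `aperture` mm at the reference distance `dref` mm (Gaussian-edged with
#' penumbra `edge_sigma`), a dimensionless fluence `weight`, and an
#' effective attenuation coefficient `mu` per mm water-equivalent.
#'
#' @param source,aim numeric length-3 world points (mm); must differ.
#' @param aperture aperture radius (mm) at `dref`.
#' @param weight fluence weight, >= 0.
#' @param mu effective attenuation per mm water-equivalent, > 0.
#' @param dref reference distance (mm) for inverse-square and aperture
#'   scaling.
#' @return An object of class `beam_spec`.
#' @export
beam_spec <- function(source, aim, aperture, weight = 1, mu = 0.005,
                      dref = 1000) {
  source <- as.numeric(source); aim <- as.numeric(aim)
  if (all(source == aim)) stopf("beam source and aim point coincide")
  if (weight < 0) stopf("beam weight must be >= 0")
  if (mu <= 0) stopf("mu must be > 0")
  structure(list(source = source, aim = aim, aperture = as.numeric(aperture),
                 weight = as.numeric(weight), mu = as.numeric(mu),
                 dref = as.numeric(dref)),
            class = "beam_spec")
}

#' Treatment plan for the simplified dose engine
#'
#' @param beams list of [beam_spec()]s (>= 1).
#' @param style `"arc"` (coplanar equispaced gantry angles) or `"robotic"`
#'   (non-isocentric beams from a superior hemisphere).
#' @param prescription prescription dose in Gy, > 0.
#' @param edge_sigma aperture penumbra (mm).
#' @return An object of class `dose_plan`.
#' @export
dose_plan <- function(beams, style = c("arc", "robotic"), prescription = 40,
                      edge_sigma = 2) {
  style <- match.arg(style)
  if (!length(beams)) stopf("a plan needs at least one beam")
  if (!all(vapply(beams, inherits, TRUE, "beam_spec")))
    stopf("`beams` must be beam_spec objects")
  if (prescription <= 0) stopf("prescription must be > 0")
  structure(list(beams = beams, style = style,
                 prescription = as.numeric(prescription),
                 edge_sigma = as.numeric(edge_sigma),
                 normalized = FALSE),
            class = "dose_plan")
}

#' @export
print.dose_plan <- function(x, ...) {
  cat(sprintf("<dose_plan> %s, %d beams, prescription %g Gy%s\n", x$style,
              length(x$beams), x$prescription,
              if (isTRUE(x$normalized)) " (normalized: D95(PTV) = prescription)" else ""))
  invisible(x)
}

plan_matrices <- function(plan) {
  list(src = do.call(rbind, lapply(plan$beams, `[[`, "source")),
       aim = do.call(rbind, lapply(plan$beams, `[[`, "aim")),
       weight = vapply(plan$beams, `[[`, 0, "weight"),
       mu = vapply(plan$beams, `[[`, 0, "mu"),
       aperture = vapply(plan$beams, `[[`, 0, "aperture"),
       dref = vapply(plan$beams, `[[`, 0, "dref"))
}

#' Compute dose on a density volume
#'
#' Deterministic forward dose: for each voxel inside the body,
#' `D(v) = sum_b w_b (dref/d)^2 exp(-mu_b RPL(source_b -> v)) A_b(v)`, with
#' `d` the source distance, `RPL` the Siddon radiological path length and
#' `A` a Gaussian-edged circular aperture transmission. Voxels outside the
#' body receive zero. Units are Gy once the plan has been normalized.
#'
#' @param plan a [dose_plan()].
#' @param red a [volume3d()] of relative electron density.
#' @param body logical mask on the same grid.
#' @return A [volume3d()] dose grid of class `c("dose_volume", "volume3d")`
#'   carrying the plan style and normalization as attributes.
#' @export
compute_dose <- function(plan, red, body) {
  stopifnot(inherits(plan, "dose_plan"), inherits(red, "volume3d"))
  if (!identical(dim(body), dim(red$values)))
    stopf("body mask is not on the density grid")
  pm <- plan_matrices(plan)
  if (all(pm$weight == 0)) stopf("plan has all-zero beam weights")
  vals <- cpp_compute_dose(red$values, dim(red$values), red$spacing,
                           red$origin, body, pm$src, pm$aim, pm$weight,
                           pm$mu, pm$aperture, pm$dref, plan$edge_sigma)
  out <- vol_like(red, vals)
  class(out) <- c("dose_volume", "volume3d")
  attr(out, "style") <- plan$style
  attr(out, "prescription") <- plan$prescription
  out
}

# deterministic spherical Fibonacci directions on the upper cap
# (polar angle within [0, theta_max]), optionally rotated in azimuth
fibonacci_hemisphere <- function(n, theta_max = 80 * pi / 180, phi0 = 0) {
  k <- seq_len(n)
  z <- 1 - (1 - cos(theta_max)) * (k - 0.5) / n
  r <- sqrt(pmax(0, 1 - z^2))
  golden <- pi * (3 - sqrt(5))
  phi <- phi0 + golden * (k - 1)
  cbind(x = r * cos(phi), y = r * sin(phi), z = z)
}

#' Build an arc or robotic plan aimed at a target
#'
#' `"arc"` places `n_beams` sources at equispaced coplanar gantry angles on a
#' circle of radius `sad` in the target's axial plane, all aimed at the PTV
#' centroid (isocentric). `"robotic"` places sources at `sad` along seeded
#' quasi-random directions on a superior hemisphere (spherical Fibonacci
#' directions with a seeded azimuth offset), each aimed at an independently
#' jittered point inside the PTV (non-isocentric). The aperture radius is
#' the PTV's bounding radius plus `margin`. Beam weights are then normalized
#' in one step so that D95 of the PTV equals the prescription on the
#' planning density volume; the weights are frozen thereafter, so
#' recomputing the plan on another volume uses identical plan parameters.
#'
#' @param style `"arc"` or `"robotic"`.
#' @param ptv logical PTV mask (non-empty) on the grid of `red`.
#' @param red planning [volume3d()] of relative electron density.
#' @param body logical body mask.
#' @param n_beams number of beams (default 36 arc, 48 robotic).
#' @param prescription prescription dose in Gy.
#' @param sad source-axis distance mm (default 1000 arc, 800 robotic).
#' @param margin aperture margin (mm) beyond the PTV bounding radius.
#' @param mu effective attenuation per mm water-equivalent.
#' @param seed integer seed for the robotic geometry draws.
#' @return A normalized [dose_plan()].
#' @export
make_plan <- function(style = c("arc", "robotic"), ptv, red, body,
                      n_beams = NULL, prescription = 40, sad = NULL,
                      margin = 5, mu = 0.005, seed = 1L) {
  style <- match.arg(style)
  stopifnot(inherits(red, "volume3d"))
  if (!any(ptv)) stopf("PTV mask is empty")
  n_beams <- n_beams %||% if (style == "arc") 36L else 48L
  sad <- sad %||% if (style == "arc") 1000 else 800
  idx <- which(ptv, arr.ind = TRUE)
  ctr <- red$origin + (colMeans(idx) - 1) * red$spacing
  pos <- sweep(sweep(idx - 1, 2, red$spacing, `*`), 2, red$origin, `+`)
  bound_r <- sqrt(max(rowSums(sweep(pos, 2, ctr, `-`)^2)))
  aperture <- bound_r + margin

  if (style == "arc") {
    ang <- 2 * pi * (seq_len(n_beams) - 1) / n_beams
    beams <- lapply(seq_len(n_beams), function(b) {
      src <- ctr + c(sad * cos(ang[b]), sad * sin(ang[b]), 0)
      beam_spec(src, ctr, aperture, weight = 1, mu = mu, dref = sad)
    })
  } else {
    draws <- with_seed(seed, list(phi0 = stats::runif(1, 0, 2 * pi),
                                  rows = sample.int(nrow(pos), n_beams,
                                                    replace = TRUE)))
    dirs <- fibonacci_hemisphere(n_beams, phi0 = draws$phi0)
    beams <- lapply(seq_len(n_beams), function(b) {
      aim <- pos[draws$rows[b], ]
      src <- aim + dirs[b, ] * sad
      beam_spec(src, aim, aperture, weight = 1, mu = mu, dref = sad)
    })
  }
  plan <- dose_plan(beams, style, prescription)

  dose <- compute_dose(plan, red, body)
  d95 <- dvh_metric(compute_dvh(dose, ptv), 95)
  if (!is.finite(d95) || d95 <= 0)
    stopf("target is unreachable: D95(PTV) is zero on the planning volume")
  scale <- prescription / d95
  plan$beams <- lapply(plan$beams, function(b) { b$weight <- b$weight * scale; b })
  plan$normalized <- TRUE
  plan
}

#' Serialize a plan as YAML
#'
#' @param plan a [dose_plan()].
#' @param path YAML path.
#' @return `write_plan` returns `path` invisibly; `read_plan` the plan.
#' @export
write_plan <- function(plan, path) {
  stopifnot(inherits(plan, "dose_plan"))
  obj <- list(style = plan$style, prescription = plan$prescription,
              edge_sigma = plan$edge_sigma, normalized = plan$normalized,
              beams = lapply(plan$beams, function(b)
                list(source = b$source, aim = b$aim, aperture = b$aperture,
                     weight = b$weight, mu = b$mu, dref = b$dref)))
  yaml::write_yaml(obj, path, precision = 17)
  invisible(path)
}

#' @rdname write_plan
#' @export
read_plan <- function(path) {
  obj <- yaml::read_yaml(path)
  beams <- lapply(obj$beams, function(b)
    beam_spec(unlist(b$source), unlist(b$aim), b$aperture, b$weight, b$mu,
              b$dref))
  plan <- dose_plan(beams, obj$style, obj$prescription, obj$edge_sigma)
  plan$normalized <- isTRUE(obj$normalized)
  plan
}
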