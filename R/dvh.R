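#' Cumulative dose-volume histogram of a structure
#'
#' Stores the structure's voxel doses and a cumulative table of the volume
#' fraction receiving at least each dose level. Dx metrics (dose to the
#' hottest x% of the volume) are obtained by inverse lookup with linear
#' interpolation between sorted dose samples (the type-7 empirical quantile
#' at probability `1 - x/100`), and checked in the test suite against a
#' sort-based oracle.
#'
#' @param dose a dose [volume3d()].
#' @param mask non-empty logical mask on the dose grid.
#' @param bins number of dose bins for the cumulative table.
#' @param name structure name carried in the result.
#' @return An object of class `dvh` with elements `name`, `doses` (sorted
#'   increasing), `table` (`dose`, `volume_fraction`), `n_voxels`.
#' @export
compute_dvh <- function(dose, mask, bins = 200L, name = "structure") {
  stopifnot(inherits(dose, "volume3d"))
  if (!identical(dim(mask), dim(dose$values)))
    stopf("mask is not on the dose grid")
  if (!any(mask)) stopf("empty mask: cannot compute a DVH")
  d <- sort(dose$values[mask])
  edges <- seq(0, max(d, 1e-12), length.out = bins)
  # fraction of voxels receiving >= each edge dose
  frac <- 1 - (findInterval(edges, d, left.open = TRUE)) / length(d)
  structure(list(name = name, doses = d,
                 table = data.frame(dose = edges, volume_fraction = frac),
                 n_voxels = length(d)),
            class = "dvh")
}

#' @export
print.dvh <- function(x, ...) {
  cat(sprintf("<dvh> %s: %d voxels, D95 %.3f / D50 %.3f / D5 %.3f Gy\n",
              x$name, x$n_voxels, dvh_metric(x, 95), dvh_metric(x, 50),
              dvh_metric(x, 5)))
  invisible(x)
}

#' @export
plot.dvh <- function(x, ..., add = FALSE, col = 1) {
  if (add) graphics::lines(x$table$dose, 100 * x$table$volume_fraction, col = col, ...)
  else graphics::plot(x$table$dose, 100 * x$table$volume_fraction, type = "l",
                      xlab = "dose (Gy)", ylab = "volume (%)", ylim = c(0, 100),
                      col = col, main = x$name, ...)
  invisible(x)
}

#' Dx metric from a DVH
#'
#' Dose received by at least x% of the structure volume.
#'
#' @param dvh a [compute_dvh()] object.
#' @param x percentage volume in (0, 100].
#' @return Dose in the grid's units (Gy).
#' @export
dvh_metric <- function(dvh, x) {
  stopifnot(inherits(dvh, "dvh"), x > 0, x <= 100)
  unname(stats::quantile(dvh$doses, probs = 1 - x / 100, type = 7))
}

#' Vx metric from a DVH
#'
#' Fraction of the structure volume receiving at least dose `d`.
#'
#' @param dvh a [compute_dvh()] object.
#' @param d dose threshold.
#' @return Volume fraction in \[0, 1\].
#' @export
dvh_volume_at <- function(dvh, d) {
  mean(dvh$doses >= d)
}

#' D95 target-coverage ratio
#'
#' `100 * D95(sCT dose) / D95(CT dose)` over the PTV: the headline measure
#' of how well a plan recomputed on the synthetic CT covers the target
#' relative to the CT-computed plan.
#'
#' @param dose_sct,dose_ct co-registered dose [volume3d()]s.
#' @param ptv logical PTV mask.
#' @return Percentage (100 means identical coverage).
#' @export
d95_ratio <- function(dose_sct, dose_ct, ptv) {
  check_coregistered(dose_sct, dose_ct, "dose volumes")
  d95s <- dvh_metric(compute_dvh(dose_sct, ptv, name = "PTV"), 95)
  d95c <- dvh_metric(compute_dvh(dose_ct, ptv, name = "PTV"), 95)
  100 * d95s / d95c
}
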