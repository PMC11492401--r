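#' HU to relative-electron-density calibration curve
#'
#' A tabulated, monotone mapping from Hounsfield units to relative electron
#' density (RED, water = 1), the object a treatment planning system consumes
#' when converting an image to a density grid. Anchors are strictly
#' increasing in HU and non-decreasing in RED; evaluation is piecewise
#' linear between anchors, constant below the lowest anchor, and a linear
#' continuation of the last segment above the highest anchor, clamped at
#' `red_max` (guards against unphysical densities from e.g. metal fiducial
#' HU).
#'
#' @param hu numeric, strictly increasing anchor HU values.
#' @param red numeric, non-negative, non-decreasing anchor RED values.
#' @param provenance one of `"original"`, `"optimized"`, `"custom"`.
#' @param red_max upper clamp for extrapolation above the last anchor.
#' @param classes optional character vector naming the tissue class of each
#'   anchor.
#' @return An object of class `calibration_curve`.
#' @seealso [build_original_curve()], [derive_optimized_curve()],
#'   [predict.calibration_curve()]
#' @export
calibration_curve <- function(hu, red, provenance = "custom", red_max = 3,
                              classes = NULL) {
  hu <- as.numeric(hu); red <- as.numeric(red)
  if (length(hu) < 2L || length(hu) != length(red))
    stopf("need at least two (hu, red) anchor pairs of equal length")
  if (any(!is.finite(hu)) || any(!is.finite(red)))
    stopf("anchors must be finite")
  if (any(duplicated(hu))) stopf("duplicate HU anchors")
  if (any(diff(hu) <= 0)) stopf("anchor HU must be strictly increasing")
  if (any(red < 0)) stopf("relative electron density must be non-negative")
  if (any(diff(red) < 0))
    stopf("non-monotone anchors: relative electron density must be non-decreasing with HU")
  if (!is.null(classes) && length(classes) != length(hu))
    stopf("`classes` must match the number of anchors")
  structure(list(hu = hu, red = red,
                 interpolation = "linear",
                 extrapolation = list(below = "constant",
                                      above = "linear_clamped",
                                      red_max = red_max),
                 provenance = provenance,
                 classes = classes),
            class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("<calibration_curve> (%s), %d anchors, linear interpolation\n",
              x$provenance, length(x$hu)))
  tab <- data.frame(hu = x$hu, red = x$red)
  if (!is.null(x$classes)) tab <- cbind(class = x$classes, tab)
  print(tab, row.names = FALSE)
  cat(sprintf("  below %g HU: constant; above %g HU: linear, clamped at RED %g\n",
              x$hu[1], x$hu[length(x$hu)], x$extrapolation$red_max))
  invisible(x)
}

#' @export
coef.calibration_curve <- function(object, ...) {
  m <- cbind(hu = object$hu, red = object$red)
  rownames(m) <- object$classes %||% rep("", nrow(m))
  m
}

#' Evaluate a calibration curve
#'
#' Maps HU to relative electron density: exact anchor HU return their anchor
#' RED; between anchors, linear interpolation; below the lowest anchor, the
#' lowest RED; above the highest anchor, linear continuation of the last
#' segment clamped at the configured maximum.
#'
#' @param object a [calibration_curve()].
#' @param hu a numeric vector/array or a [volume3d()] of HU; must be finite.
#' @param ... unused.
#' @return RED values of the same shape as `hu` (a [volume3d()] in, a
#'   [volume3d()] out).
#' @export
predict.calibration_curve <- function(object, hu, ...) {
  if (inherits(hu, "volume3d"))
    return(vol_like(hu, predict(object, hu$values)))
  if (any(!is.finite(hu))) stopf("non-finite HU passed to calibration curve")
  n <- length(object$hu)
  out <- stats::approx(object$hu, object$red, xout = as.numeric(hu),
                       method = "linear", rule = 2)$y
  above <- hu > object$hu[n]
  if (any(above)) {
    slope <- (object$red[n] - object$red[n - 1]) /
             (object$hu[n] - object$hu[n - 1])
    out[above] <- pmin(object$red[n] + slope * (hu[above] - object$hu[n]),
                       object$extrapolation$red_max)
  }
  if (is.array(hu)) dim(out) <- dim(hu)
  out
}

#' @export
plot.calibration_curve <- function(x, ..., hu_range = NULL) {
  hu_range <- hu_range %||% range(x$hu) + c(-100, 300)
  grid <- seq(hu_range[1], hu_range[2], length.out = 400)
  graphics::plot(grid, predict(x, grid), type = "l",
                 xlab = "HU", ylab = "relative electron density",
                 main = sprintf("Calibration curve (%s)", x$provenance), ...)
  graphics::points(x$hu, x$red, pch = 19)
  invisible(x)
}

#' Original (vendor bulk-assignment) calibration curve
#'
#' Anchors at the five sCT bulk HU values, each paired with its class
#' relative electron density.
#'
#' @param classes a tissue class scheme, see [tissue_classes()].
#' @param red_max extrapolation clamp.
#' @return A [calibration_curve()] with provenance `"original"`.
#' @export
build_original_curve <- function(classes = tissue_classes(), red_max = 3) {
  cls <- classes_ordered(classes)
  ord <- order(cls$sct_bulk_hu)
  calibration_curve(cls$sct_bulk_hu[ord], cls$red[ord],
                    provenance = "original", red_max = red_max,
                    classes = cls$name[ord])
}

#' Aggregate per-patient class statistics over a cohort
#'
#' Cohort class means are, by default, the unweighted mean of per-patient
#' class means ("averaged across all patient CTs"), which is robust to
#' body-size differences; a voxel-pooled mode is available. The
#' between-patient standard deviation of the per-patient means and its
#' standard error are retained for downstream tolerance checks.
#'
#' @param stats_list list of per-patient data.frames from [class_hu_stats()].
#' @param aggregation `"patient_mean"` (default) or `"pooled"`.
#' @return An object of class `cohort_stats`: a data.frame with columns
#'   `class`, `mean_hu`, `sd_between`, `se_mean`, `n_patients`, plus the
#'   per-patient mean matrix as attribute `per_patient`.
#' @export
cohort_class_stats <- function(stats_list, aggregation = c("patient_mean", "pooled")) {
  aggregation <- match.arg(aggregation)
  if (!length(stats_list)) stopf("empty cohort")
  nms <- tissue_class_names()
  pm <- sapply(stats_list, function(s) s$mean_hu[match(nms, s$class)])
  pn <- sapply(stats_list, function(s) s$n_voxels[match(nms, s$class)])
  if (is.null(dim(pm))) { pm <- matrix(pm, ncol = 1); pn <- matrix(pn, ncol = 1) }
  rownames(pm) <- nms
  mean_hu <- if (aggregation == "patient_mean") rowMeans(pm)
             else rowSums(pm * pn) / rowSums(pn)
  sd_between <- apply(pm, 1, stats::sd)
  n_pat <- ncol(pm)
  out <- data.frame(class = nms, mean_hu = as.numeric(mean_hu),
                    sd_between = if (n_pat > 1) sd_between else 0,
                    se_mean = if (n_pat > 1) sd_between / sqrt(n_pat) else 0,
                    n_patients = n_pat, stringsAsFactors = FALSE)
  attr(out, "per_patient") <- pm
  attr(out, "aggregation") <- aggregation
  class(out) <- c("cohort_stats", "data.frame")
  out
}

#' Derive the cohort-optimized calibration curve
#'
#' Builds the optimized HU-to-RED curve from cohort CT statistics: anchors at
#' (air -1000, adipose cohort mean, soft-tissue cohort mean, inner bone,
#' outer bone), each paired with its configured class RED. With
#' `keep_sct_bone = TRUE` (the default) the two bone anchors are taken from
#' the sCT bulk scheme (204 and 1170 HU) because bulk sCT bone values already
#' lie within the literature range and are left unmodified; with
#' `keep_sct_bone = FALSE` the bone anchors are the cohort CT means,
#' yielding the CT-commissioned clinical curve.
#'
#' @param cohort a [cohort_class_stats()] object covering all five classes.
#' @param red_by_class optional named numeric of per-class REDs; defaults to
#'   the `red` column of `classes`.
#' @param keep_sct_bone keep bone anchors at the sCT bulk values.
#' @param classes tissue class scheme supplying sCT bulk values and default
#'   REDs.
#' @param red_max extrapolation clamp.
#' @return A [calibration_curve()] with provenance `"optimized"`.
#' @export
derive_optimized_curve <- function(cohort, red_by_class = NULL,
                                   keep_sct_bone = TRUE,
                                   classes = tissue_classes(), red_max = 3) {
  if (!inherits(cohort, "cohort_stats")) stopf("`cohort` must be cohort_stats")
  cls <- classes_ordered(classes)
  nms <- tissue_class_names()
  if (!all(nms %in% cohort$class) || any(!is.finite(cohort$mean_hu)))
    stopf("cohort must contain finite statistics for all five classes")
  red <- cls$red
  names(red) <- cls$name
  if (!is.null(red_by_class)) red[names(red_by_class)] <- red_by_class
  hu <- c(air = -1000,
          adipose = cohort$mean_hu[cohort$class == "adipose"],
          soft_tissue = cohort$mean_hu[cohort$class == "soft_tissue"],
          inner_bone = if (keep_sct_bone) cls$sct_bulk_hu[cls$name == "inner_bone"]
                       else cohort$mean_hu[cohort$class == "inner_bone"],
          outer_bone = if (keep_sct_bone) cls$sct_bulk_hu[cls$name == "outer_bone"]
                       else cohort$mean_hu[cohort$class == "outer_bone"])
  if (any(diff(hu) <= 0))
    stopf("implausible cohort: derived anchors are not strictly increasing in HU")
  calibration_curve(as.numeric(hu), as.numeric(red[nms]),
                    provenance = "optimized", red_max = red_max, classes = nms)
}

#' Serialize a calibration curve
#'
#' The anchor table is written as a two-column CSV
#' (`hu, relative_electron_density`) with a JSON sidecar
#' (`<path>.json`) recording the interpolation and extrapolation rules and
#' the provenance, the importable shape for TPS-style tabulated curves.
#'
#' @param curve a [calibration_curve()].
#' @param path CSV path; the sidecar is written next to it.
#' @return `write_calibration` returns `path` invisibly; `read_calibration`
#'   returns the curve.
#' @export
write_calibration <- function(curve, path) {
  stopifnot(inherits(curve, "calibration_curve"))
  # %.17g keeps doubles bit-exact through the text round trip
  df <- data.frame(hu = sprintf("%.17g", curve$hu),
                   relative_electron_density = sprintf("%.17g", curve$red))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  meta <- list(interpolation = curve$interpolation,
               extrapolation = curve$extrapolation,
               provenance = curve$provenance,
               classes = curve$classes)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  df <- utils::read.csv(path)
  meta <- jsonlite::read_json(paste0(path, ".json"))
  calibration_curve(df$hu, df$relative_electron_density,
                    provenance = meta$provenance %||% "custom",
                    red_max = meta$extrapolation$red_max %||% 3,
                    classes = if (!is.null(meta$classes)) unlist(meta$classes))
}
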