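#' Intensity threshold scheme for five-class segmentation
#'
#' Four strictly increasing HU cut points separate air, adipose, soft
#' tissue, inner bone and outer bone. Defaults are the midpoints between
#' adjacent CT class means of the default [tissue_classes()] scheme
#' (-548, -29.5, 128, 609.5 HU), the symmetric choice when no thresholds
#' are prescribed. `opening_radius` controls the morphological opening (in
#' voxels, Euclidean ball) applied per class to drop boundary and
#' partial-volume voxels; 0 disables it.
#'
#' @param boundaries numeric length-4, strictly increasing HU cut points.
#' @param opening_radius non-negative integer voxel radius.
#' @return An object of class `threshold_scheme`.
#' @export
threshold_scheme <- function(boundaries = c(-548, -29.5, 128, 609.5),
                             opening_radius = 1L) {
  boundaries <- as.numeric(boundaries)
  if (length(boundaries) != 4L || any(!is.finite(boundaries)))
    stopf("`boundaries` must be 4 finite HU values")
  if (any(diff(boundaries) <= 0))
    stopf("`boundaries` must be strictly increasing")
  if (opening_radius < 0) stopf("`opening_radius` must be >= 0")
  structure(list(boundaries = boundaries,
                 opening_radius = as.integer(opening_radius)),
            class = "threshold_scheme")
}

# integer offsets of a Euclidean ball of the given voxel radius
ball_offsets <- function(radius) {
  r <- as.integer(radius)
  off <- expand.grid(dx = -r:r, dy = -r:r, dz = -r:r)
  off <- off[off$dx^2 + off$dy^2 + off$dz^2 <= r^2, , drop = FALSE]
  as.matrix(off)
}

# shift a logical array by integer voxel offsets, padding with `fill`
shift_mask <- function(m, d, fill = FALSE) {
  shp <- dim(m)
  out <- array(fill, dim = shp)
  src <- dst <- vector("list", 3L)
  for (a in 1:3) {
    if (d[a] >= 0) {
      if (d[a] >= shp[a]) return(out)
      src[[a]] <- seq_len(shp[a] - d[a])
      dst[[a]] <- src[[a]] + d[a]
    } else {
      if (-d[a] >= shp[a]) return(out)
      src[[a]] <- seq.int(1 - d[a], shp[a])
      dst[[a]] <- src[[a]] + d[a]
    }
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- m[src[[1]], src[[2]], src[[3]]]
  out
}

erode_mask <- function(m, offsets) {
  out <- m
  for (r in seq_len(nrow(offsets))) {
    d <- offsets[r, ]
    if (all(d == 0)) next
    out <- out & shift_mask(m, d, fill = FALSE)
  }
  out
}

dilate_mask <- function(m, offsets) {
  out <- m
  for (r in seq_len(nrow(offsets))) {
    d <- offsets[r, ]
    if (all(d == 0)) next
    out <- out | shift_mask(m, d, fill = FALSE)
  }
  out
}

# morphological opening (erosion then dilation); anti-extensive, so the
# result is always a subset of the input mask
open_mask <- function(m, radius) {
  if (radius <= 0) return(m)
  off <- ball_offsets(radius)
  dilate_mask(erode_mask(m, off), off)
}

#' Segment a CT volume into five tissue classes
#'
#' Assigns every voxel to exactly one class by its HU interval, then
#' optionally applies a per-class morphological opening that flags boundary
#' voxels as unclassified (they are removed from their class, never
#' reassigned to another). The returned structure set carries the five class
#' masks plus an `unclassified` mask; before opening the class masks
#' partition the grid.
#'
#' @param ct a [volume3d()] with finite HU values.
#' @param scheme a [threshold_scheme()].
#' @return A [structure_set()] with masks `air`, `adipose`, `soft_tissue`,
#'   `inner_bone`, `outer_bone`, `unclassified`.
#' @examples
#' ct <- volume3d(array(c(-500, 20, 700), c(3, 1, 1)))
#' s <- segment_classes(ct, threshold_scheme(opening_radius = 0))
#' which(s$masks$adipose)  # voxel 1
#' @export
segment_classes <- function(ct, scheme = threshold_scheme()) {
  stopifnot(inherits(ct, "volume3d"), inherits(scheme, "threshold_scheme"))
  if (any(!is.finite(ct$values))) stopf("CT contains non-finite HU values")
  shp <- dim(ct$values)
  lab <- findInterval(ct$values, scheme$boundaries) + 1L
  dim(lab) <- shp
  nms <- tissue_class_names()
  masks <- lapply(seq_along(nms), function(i) lab == i)
  names(masks) <- nms
  if (scheme$opening_radius > 0)
    masks <- lapply(masks, open_mask, radius = scheme$opening_radius)
  masks$unclassified <- !Reduce(`|`, masks[nms])
  structure_set(masks, ct$spacing, ct$origin)
}

#' Per-class HU statistics
#'
#' Mean and population (divide-by-N) standard deviation of the CT HU over
#' each class mask. Empty masks are reported with `n_voxels = 0` and `NA`
#' moments, and flagged in the `empty` column.
#'
#' @param ct a [volume3d()].
#' @param masks a [structure_set()] on the same grid (any subset of masks
#'   named after tissue classes is used; other masks are ignored).
#' @return A data.frame with columns `class`, `mean_hu`, `sd_hu`,
#'   `n_voxels`, `empty`.
#' @export
class_hu_stats <- function(ct, masks) {
  stopifnot(inherits(ct, "volume3d"), inherits(masks, "structure_set"))
  if (!identical(dim(ct$values), ss_shape(masks)))
    stopf("mask shape (%s) does not match CT shape (%s)",
          paste(ss_shape(masks), collapse = "x"),
          paste(dim(ct$values), collapse = "x"))
  nms <- intersect(tissue_class_names(), names(masks$masks))
  rows <- lapply(nms, function(nm) {
    v <- ct$values[masks$masks[[nm]]]
    data.frame(class = nm,
               mean_hu = if (length(v)) mean(v) else NA_real_,
               sd_hu = sd_pop(v),
               n_voxels = length(v),
               empty = length(v) == 0L,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Write class statistics as CSV
#'
#' Emits the `class, mean_hu, sd_hu, n_voxels` table.
#'
#' @param stats output of [class_hu_stats()] (or a cohort aggregate).
#' @param path CSV path.
#' @export
write_class_stats <- function(stats, path) {
  utils::write.csv(stats, path, row.names = FALSE)
  invisible(path)
}
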