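#' Three-dimensional scalar volume with grid metadata
#'
#' The basic container used throughout the package for HU, relative
#' electron density and dose grids: a 3D array of voxel values plus the
#' voxel spacing and the world position of the centre of voxel `(1,1,1)`.
#'
#' The coordinate convention, used everywhere in the package, is: voxel
#' indices are 1-based in R (0-based internally in compiled code); the world
#' position of voxel `(i,j,k)` is `origin + (c(i,j,k) - 1) * spacing`, in mm;
#' axes are ordered (x, y, z) = (right, anterior, superior). Two volumes are
#' *co-registered* iff their shape, spacing and origin are all equal.
#'
#' @param values numeric 3D array of voxel values (HU, RED or Gy).
#' @param spacing numeric length-3, mm per axis; strictly positive.
#' @param origin numeric length-3, world mm of the centre of the first voxel.
#'   Default centres the grid on the world origin.
#' @return An object of class `volume3d`.
#' @examples
#' v <- volume3d(array(0, c(4, 4, 2)), spacing = c(2, 2, 3))
#' v$spacing
#' @export
volume3d <- function(values, spacing = c(1, 1, 1), origin = NULL) {
  if (!is.array(values) || length(dim(values)) != 3L)
    stopf("`values` must be a 3D array")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stopf("`spacing` must be 3 strictly positive numbers (mm)")
  if (is.null(origin)) origin <- -(dim(values) - 1) / 2 * spacing
  origin <- as.numeric(origin)
  if (length(origin) != 3L || any(!is.finite(origin)))
    stopf("`origin` must be 3 finite numbers (mm)")
  structure(list(values = values, spacing = spacing, origin = origin),
            class = "volume3d")
}

#' @export
print.volume3d <- function(x, ...) {
  cat(sprintf("<volume3d> %s voxels @ %s mm, origin (%s) mm\n",
              paste(dim(x$values), collapse = "x"),
              paste(format(x$spacing), collapse = "x"),
              paste(format(x$origin), collapse = ", ")))
  v <- x$values[is.finite(x$values)]
  if (length(v))
    cat(sprintf("  values: range [%.6g, %.6g], mean %.6g\n",
                min(v), max(v), mean(v)))
  invisible(x)
}

vol_shape <- function(vol) dim(vol$values)

# world coordinates of voxel centres along one axis
axis_coords <- function(vol, axis) {
  vol$origin[axis] + (seq_len(dim(vol$values)[axis]) - 1) * vol$spacing[axis]
}

# a new volume on the same grid
vol_like <- function(vol, values) volume3d(values, vol$spacing, vol$origin)

#' Check that two volumes share a grid
#'
#' Errors naming the first differing attribute (shape, spacing or origin)
#' when the volumes are not co-registered.
#'
#' @param a,b `volume3d` objects.
#' @param what label used in the error message.
#' @return Invisibly `TRUE`.
#' @export
check_coregistered <- function(a, b, what = "volumes") {
  if (!inherits(a, "volume3d") || !inherits(b, "volume3d"))
    stopf("%s must be volume3d objects", what)
  if (!identical(dim(a$values), dim(b$values)))
    stopf("%s are not co-registered: shape differs (%s vs %s)", what,
          paste(dim(a$values), collapse = "x"),
          paste(dim(b$values), collapse = "x"))
  if (!isTRUE(all.equal(a$spacing, b$spacing, tolerance = 1e-12)))
    stopf("%s are not co-registered: spacing differs", what)
  if (!isTRUE(all.equal(a$origin, b$origin, tolerance = 1e-12)))
    stopf("%s are not co-registered: origin differs", what)
  invisible(TRUE)
}

#' Read and write volumes as NIfTI-1
#'
#' Volumes are stored as float32 NIfTI with the spacing in `pixdim` and the
#' origin in the sform translation.
#'
#' @param vol a `volume3d`.
#' @param path file path (`.nii` or `.nii.gz`).
#' @return `write_volume` returns `path` invisibly; `read_volume` returns a
#'   `volume3d`.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "volume3d"))
  img <- RNifti::asNifti(vol$values, datatype = "float")
  m <- rbind(cbind(diag(vol$spacing), vol$origin), c(0, 0, 0, 1))
  img <- RNifti::`sform<-`(img, structure(m, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  m <- RNifti::xform(img)
  vals <- array(as.numeric(img), dim = dim(img))
  volume3d(vals, spacing = abs(diag(m[1:3, 1:3])), origin = as.numeric(m[1:3, 4]))
}
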