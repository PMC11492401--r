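#' Signed HU difference map
#'
#' Voxelwise `CT - sCT` on the shared grid (the orientation used for
#' rendering difference maps; for display, clip to +/-150 HU — never for
#' computation).
#'
#' @param ct,sct co-registered [volume3d()] volumes.
#' @return A [volume3d()] of signed HU differences.
#' @export
difference_map <- function(ct, sct) {
  check_coregistered(ct, sct, "CT and sCT")
  vol_like(ct, ct$values - sct$values)
}

#' Mean absolute HU error
#'
#' `MAE = (1/N) * sum_i |sCT(i) - CT(i)|` over all voxels, or over an
#' optional mask. Symmetric in its two volume arguments.
#'
#' @param a,b co-registered [volume3d()] volumes.
#' @param mask optional logical array on the same grid; must be non-empty.
#' @return Scalar MAE in HU.
#' @export
mae <- function(a, b, mask = NULL) {
  check_coregistered(a, b)
  d <- abs(a$values - b$values)
  if (is.null(mask)) return(mean(d))
  if (!identical(dim(mask), dim(a$values)))
    stopf("mask shape does not match volume shape")
  if (!any(mask)) stopf("empty mask in MAE computation")
  mean(d[mask])
}

#' Override class HU values in a volume
#'
#' Sets every voxel of each named class mask to the given HU (a bulk HU
#' override, as used to build "modified" sCTs whose class values match the
#' cohort CT means). Voxels outside the named masks, and the input volume
#' itself, are untouched.
#'
#' @param sct a [volume3d()].
#' @param masks a [structure_set()] on the same grid.
#' @param new_hu_by_class named numeric, e.g.
#'   `c(adipose = -96, soft_tissue = 37)`. May be empty (identity).
#' @return A new [volume3d()].
#' @export
override_classes <- function(sct, masks, new_hu_by_class) {
  stopifnot(inherits(sct, "volume3d"), inherits(masks, "structure_set"))
  if (!identical(dim(sct$values), ss_shape(masks)))
    stopf("masks are not on the sCT grid")
  vals <- sct$values
  for (nm in names(new_hu_by_class)) {
    if (!nm %in% names(masks$masks))
      stopf("no mask named '%s' in the structure set", nm)
    vals[masks$masks[[nm]]] <- new_hu_by_class[[nm]]
  }
  vol_like(sct, vals)
}

#' Suppress small-metal HU before planning
#'
#' Replaces voxels above a metal threshold with a tissue HU value. Gold
#' fiducial seeds (and dense calcifications) far exceed any pelvic tissue HU
#' and, in a primary-only exponential beam model, would cast hard shadows a
#' clinical scatter-handling engine smears out; overriding high-Z voxel HU
#' on the planning image is the standard treatment-planning practice this
#' step mirrors. Applied to the planning CT only — HU comparison statistics
#' keep the original values.
#'
#' @param ct a [volume3d()].
#' @param threshold_hu voxels strictly above this are overridden (default
#'   1200 HU, above any tissue class).
#' @param replacement_hu HU written into overridden voxels (default 37,
#'   soft tissue).
#' @return A new [volume3d()].
#' @export
override_metal_hu <- function(ct, threshold_hu = 1200, replacement_hu = 37) {
  stopifnot(inherits(ct, "volume3d"))
  vals <- ct$values
  vals[vals > threshold_hu] <- replacement_hu
  vol_like(ct, vals)
}

# segment an sCT's own bulk classes (exact: piecewise-constant input)
sct_class_masks <- function(sct, scheme = threshold_scheme(opening_radius = 0L)) {
  segment_classes(sct, scheme)
}

#' Cohort MAE table (original versus modified sCT)
#'
#' For every cohort member, computes total, soft-tissue, adipose and
#' total-bone MAE between CT and the original sCT, and between CT and the
#' modified sCT in which the sCT's own adipose and soft-tissue classes are
#' overridden to the supplied HU values (typically the cohort CT class
#' means). Per-class MAE uses masks segmented from each patient's CT; total
#' bone is the union of inner and outer bone; total MAE is over all voxels
#' of the volume by default (`body_only = TRUE` restricts it to the body
#' mask; the choice is recorded in the result).
#'
#' @param cohort a cohort from [generate_cohort()], or any list of elements
#'   with `ct`, `sct` and `structures`.
#' @param override_hu named numeric of class HU overrides for the modified
#'   sCT, e.g. `c(adipose = -96, soft_tissue = 37)`.
#' @param scheme CT segmentation [threshold_scheme()].
#' @param body_only restrict total MAE to the body mask.
#' @return A data.frame of class `mae_table`, one row per patient plus
#'   attributes `summary` (cohort mean/sd per column) and `body_only`.
#' @export
cohort_mae_table <- function(cohort, override_hu = c(adipose = -96, soft_tissue = 37),
                             scheme = threshold_scheme(), body_only = FALSE) {
  if (!length(cohort)) stopf("empty cohort")
  rows <- lapply(seq_along(cohort), function(i) {
    p <- cohort[[i]]
    seg <- segment_classes(p$ct, scheme)
    sct_masks <- sct_class_masks(p$sct)
    sct_mod <- override_classes(p$sct, sct_masks, override_hu)
    m <- seg$masks
    bone <- m$inner_bone | m$outer_bone
    tot_mask <- if (body_only) p$structures$masks$body else NULL
    data.frame(patient = i,
               total_original = mae(p$ct, p$sct, tot_mask),
               total_modified = mae(p$ct, sct_mod, tot_mask),
               soft_tissue_original = mae(p$ct, p$sct, m$soft_tissue),
               soft_tissue_modified = mae(p$ct, sct_mod, m$soft_tissue),
               adipose_original = mae(p$ct, p$sct, m$adipose),
               adipose_modified = mae(p$ct, sct_mod, m$adipose),
               total_bone_original = mae(p$ct, p$sct, bone))
  })
  out <- do.call(rbind, rows)
  num <- out[, setdiff(names(out), "patient")]
  attr(out, "summary") <- data.frame(metric = names(num),
                                     mean = colMeans(num),
                                     sd = if (nrow(out) > 1) apply(num, 2, stats::sd)
                                          else rep(0, ncol(num)),
                                     row.names = NULL)
  attr(out, "body_only") <- body_only
  attr(out, "override_hu") <- override_hu
  class(out) <- c("mae_table", "data.frame")
  out
}

#' @export
print.mae_table <- function(x, ...) {
  cat(sprintf("<mae_table> %d patients (total MAE over %s)\n", nrow(x),
              if (isTRUE(attr(x, "body_only"))) "body voxels" else "all voxels"))
  print.data.frame(round(as.data.frame(x), 1), row.names = FALSE)
  s <- attr(x, "summary")
  cat("cohort mean +/- sd:\n")
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %-22s %6.1f +/- %.1f HU\n", s$metric[i], s$mean[i], s$sd[i]))
  invisible(x)
}
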