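#' Five-class tissue scheme for pelvis CT/sCT
#'
#' Per-class CT HU statistics, vendor synthetic-CT bulk HU assignments and
#' relative electron densities (RED, water = 1) used across the package:
#'
#' | class       | CT mean (HU) | CT sd | sCT bulk (HU) | RED   |
#' |-------------|--------------|-------|---------------|-------|
#' | air         | -1000        | 0     | -1000         | 0.001 |
#' | adipose     | -96          | 6.1   | -75           | 0.95  |
#' | soft_tissue | 37           | 3.9   | 0             | 1.04  |
#' | inner_bone  | 219          | 14    | 204           | 1.1   |
#' | outer_bone  | 1000         | 23    | 1170          | 1.7   |
#'
#' The CT column characterises patient CT intensities at 120 kVp; the sCT
#' column is the bulk value a class-assignment sCT algorithm writes for each
#' class. Air RED is set to 0.001 (near-zero, physical, avoids degenerate
#' path-length terms).
#'
#' @param ct_mean_hu,ct_std_hu,sct_bulk_hu,red optional numeric length-5
#'   overrides, ordered air, adipose, soft_tissue, inner_bone, outer_bone.
#' @return A data.frame with columns `name`, `ct_mean_hu`, `ct_std_hu`,
#'   `sct_bulk_hu`, `red`.
#' @examples
#' tissue_classes()
#' tissue_classes(ct_std_hu = rep(0, 5)) # noise-free scheme
#' @export
tissue_classes <- function(ct_mean_hu = c(-1000, -96, 37, 219, 1000),
                           ct_std_hu = c(0, 6.1, 3.9, 14, 23),
                           sct_bulk_hu = c(-1000, -75, 0, 204, 1170),
                           red = c(0.001, 0.95, 1.04, 1.1, 1.7)) {
  nm <- c("air", "adipose", "soft_tissue", "inner_bone", "outer_bone")
  cls <- data.frame(name = nm,
                    ct_mean_hu = as.numeric(ct_mean_hu),
                    ct_std_hu = as.numeric(ct_std_hu),
                    sct_bulk_hu = as.numeric(sct_bulk_hu),
                    red = as.numeric(red),
                    stringsAsFactors = FALSE)
  validate_classes(cls)
  cls
}

tissue_class_names <- function() {
  c("air", "adipose", "soft_tissue", "inner_bone", "outer_bone")
}

validate_classes <- function(cls) {
  need <- c("name", "ct_mean_hu", "ct_std_hu", "sct_bulk_hu", "red")
  if (!is.data.frame(cls) || !all(need %in% names(cls)))
    stopf("tissue class scheme must have columns %s", paste(need, collapse = ", "))
  if (anyDuplicated(cls$name)) stopf("tissue class names must be unique")
  if (!setequal(cls$name, tissue_class_names()))
    stopf("tissue class scheme must cover exactly: %s",
          paste(tissue_class_names(), collapse = ", "))
  if (any(cls$ct_std_hu < 0)) stopf("ct_std_hu must be >= 0")
  if (any(cls$red < 0)) stopf("relative electron density must be >= 0")
  invisible(cls)
}

# scheme rows in canonical order
classes_ordered <- function(cls) {
  validate_classes(cls)
  cls[match(tissue_class_names(), cls$name), , drop = FALSE]
}
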