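#' Gamma analysis criteria
#'
#' The acceptance criteria for comparing two dose distributions: a dose
#' tolerance (fraction of the normalization dose), a distance-to-agreement
#' (DTA, mm), the normalization mode (`"local"` divides the dose difference
#' by the reference voxel's own dose, `"global"` by the prescription), a
#' low-dose cutoff (fraction of the prescription below which reference
#' voxels are not evaluated), and the bounded-search geometry (search radius
#' and sub-voxel step). Defaults are 3%/3 mm local with a 10% cutoff, a
#' search radius of twice the DTA and a step of DTA/10.
#'
#' @param dose_tol dose tolerance fraction (> 0), e.g. 0.03.
#' @param dta_mm distance to agreement in mm (> 0).
#' @param norm `"local"` or `"global"`.
#' @param cutoff low-dose cutoff fraction of prescription, in \[0, 1).
#' @param search_radius_mm search radius (default `2 * dta_mm`).
#' @param step_mm sub-voxel search step (default `dta_mm / 10`).
#' @return An object of class `gamma_criteria`.
#' @export
gamma_criteria <- function(dose_tol = 0.03, dta_mm = 3, norm = c("local", "global"),
                           cutoff = 0.1, search_radius_mm = NULL, step_mm = NULL) {
  norm <- match.arg(norm)
  if (dose_tol <= 0 || dta_mm <= 0) stopf("gamma tolerances must be > 0")
  if (cutoff < 0 || cutoff >= 1) stopf("cutoff must be in [0, 1)")
  structure(list(dose_tol = dose_tol, dta_mm = dta_mm, norm = norm,
                 cutoff = cutoff,
                 search_radius_mm = search_radius_mm %||% (2 * dta_mm),
                 step_mm = step_mm %||% (dta_mm / 10)),
            class = "gamma_criteria")
}

#' @export
print.gamma_criteria <- function(x, ...) {
  cat(sprintf("<gamma_criteria> %g%%/%g mm %s, cutoff %g%% of prescription, search %g mm @ %g mm\n",
              100 * x$dose_tol, x$dta_mm, x$norm, 100 * x$cutoff,
              x$search_radius_mm, x$step_mm))
  invisible(x)
}

#' Gamma index between two dose distributions
#'
#' For each reference voxel above the low-dose cutoff,
#' `gamma = min over the search neighborhood of
#' sqrt((dD / (tol * Dnorm))^2 + (dr / DTA)^2)`, where the evaluated dose is
#' interpolated trilinearly on a sub-voxel search grid and `Dnorm` is the
#' reference voxel's own dose (local mode) or the prescription (global
#' mode). A voxel passes when `gamma <= 1`. Reference voxels whose
#' evaluated counterpart is zero receive gamma from the same formula (no
#' special-casing).
#'
#' @param reference,evaluated co-registered dose [volume3d()]s.
#' @param criteria a [gamma_criteria()].
#' @param prescription prescription dose in Gy (used for the cutoff and for
#'   global normalization); defaults to the reference volume's recorded
#'   prescription.
#' @return An object of class `gamma_result`: `gamma` (a [volume3d()] map,
#'   `NA` where not evaluated), `pass_rate` (percent), `n_evaluated`,
#'   `criteria`, `prescription`.
#' @export
gamma_index <- function(reference, evaluated, criteria = gamma_criteria(),
                        prescription = NULL) {
  check_coregistered(reference, evaluated, "dose volumes")
  stopifnot(inherits(criteria, "gamma_criteria"))
  prescription <- prescription %||% attr(reference, "prescription")
  if (is.null(prescription) || !is.finite(prescription) || prescription <= 0)
    stopf("a positive prescription dose is required for the gamma cutoff")
  res <- cpp_gamma(reference$values, evaluated$values, dim(reference$values),
                   reference$spacing, reference$origin, criteria$dose_tol,
                   criteria$dta_mm, criteria$norm == "local", prescription,
                   criteria$cutoff * prescription, criteria$search_radius_mm,
                   criteria$step_mm)
  if (res$n_evaluated == 0)
    stopf("no reference voxels above the low-dose cutoff: nothing to evaluate")
  structure(list(gamma = vol_like(reference, res$gamma),
                 pass_rate = 100 * res$n_pass / res$n_evaluated,
                 n_evaluated = res$n_evaluated,
                 criteria = criteria, prescription = prescription),
            class = "gamma_result")
}

#' @export
print.gamma_result <- function(x, ...) {
  cat(sprintf("<gamma_result> pass rate %.2f%% over %d voxels (%g%%/%g mm %s)\n",
              x$pass_rate, x$n_evaluated, 100 * x$criteria$dose_tol,
              x$criteria$dta_mm, x$criteria$norm))
  invisible(x)
}
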