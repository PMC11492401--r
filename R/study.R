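#' Configuration for a full commissioning study
#'
#' Bundles everything [run_study()] needs: the cohort definition, the
#' segmentation scheme, the tissue-class/RED scheme, the plan styles and
#' engine parameters, and the gamma criteria. The master `seed` fixes every
#' stochastic step (per-patient seeds are `seed + patient`, robotic plan
#' geometry uses a documented offset of that), so two runs with the same
#' config are bit-identical.
#'
#' @param n_patients cohort size.
#' @param seed master integer seed.
#' @param base_spec base [phantom_spec()] (per-patient jitter applies on top).
#' @param jitter relative geometry jitter, see [generate_cohort()].
#' @param scheme segmentation [threshold_scheme()].
#' @param classes tissue class scheme, see [tissue_classes()].
#' @param plan_styles subset of `c("arc", "robotic")`.
#' @param prescription prescription dose in Gy.
#' @param n_beams named list/vector of beam counts per style.
#' @param mu effective attenuation per mm water-equivalent.
#' @param criteria [gamma_criteria()] for dose comparison.
#' @param out_dir optional output directory; when set, [run_study()] writes
#'   all tables, curves and provenance there.
#' @return An object of class `study_config`.
#' @export
study_config <- function(n_patients = 10L, seed = 1L,
                         base_spec = phantom_spec(), jitter = 0.1,
                         scheme = threshold_scheme(),
                         classes = tissue_classes(),
                         plan_styles = c("arc", "robotic"),
                         prescription = 40,
                         n_beams = c(arc = 36L, robotic = 48L),
                         mu = 0.005,
                         criteria = gamma_criteria(),
                         out_dir = NULL) {
  plan_styles <- match.arg(plan_styles, c("arc", "robotic"), several.ok = TRUE)
  structure(list(n_patients = as.integer(n_patients), seed = as.integer(seed),
                 base_spec = base_spec, jitter = jitter, scheme = scheme,
                 classes = classes, plan_styles = plan_styles,
                 prescription = prescription, n_beams = n_beams, mu = mu,
                 criteria = criteria, out_dir = out_dir),
            class = "study_config")
}

#' Read a study configuration from YAML
#'
#' Recognised top-level keys: `n_patients`, `seed`, `jitter`, `shape`,
#' `spacing`, `zero_noise`, `artifacts` (mapping), `plan_styles`,
#' `prescription`, `n_beams` (mapping style -> count), `mu`, `gamma`
#' (mapping with `dose_tol`, `dta_mm`, `norm`, `cutoff`), `boundaries`,
#' `opening_radius`, `out_dir`. Missing keys take the [study_config()]
#' defaults.
#'
#' @param path YAML file.
#' @return A `study_config`.
#' @export
read_study_config <- function(path) {
  y <- yaml::read_yaml(path)
  spec_args <- list()
  if (!is.null(y$shape)) spec_args$shape <- unlist(y$shape)
  if (!is.null(y$spacing)) spec_args$spacing <- unlist(y$spacing)
  if (!is.null(y$artifacts)) spec_args$artifacts <- y$artifacts
  base_spec <- do.call(phantom_spec, spec_args)
  classes <- if (isTRUE(y$zero_noise)) tissue_classes(ct_std_hu = rep(0, 5))
             else tissue_classes()
  scheme_args <- list()
  if (!is.null(y$boundaries)) scheme_args$boundaries <- unlist(y$boundaries)
  if (!is.null(y$opening_radius)) scheme_args$opening_radius <- y$opening_radius
  crit <- if (is.null(y$gamma)) gamma_criteria()
          else do.call(gamma_criteria, y$gamma)
  args <- list(base_spec = base_spec, classes = classes,
               scheme = do.call(threshold_scheme, scheme_args),
               criteria = crit)
  for (k in c("n_patients", "seed", "jitter", "plan_styles", "prescription",
              "mu", "out_dir"))
    if (!is.null(y[[k]])) args[[k]] <- if (k == "plan_styles") unlist(y[[k]]) else y[[k]]
  if (!is.null(y$n_beams)) args$n_beams <- unlist(y$n_beams)
  do.call(study_config, args)
}

#' Run the full commissioning study on a synthetic cohort
#'
#' Executes the whole workflow the package exists for:
#' 1. simulate a seeded cohort of co-registered CT/sCT pairs;
#' 2. segment each CT into the five tissue classes and collect HU statistics;
#' 3. aggregate cohort statistics and build three calibration curves: the
#'    vendor *original* curve, the cohort-*optimized* sCT curve (bone anchors
#'    kept at the sCT bulk values) and the *CT* curve (all anchors at the
#'    cohort CT means — the clinically commissioned curve used to convert
#'    the CT itself);
#' 4. compare HU agreement (MAE) between CT and the original versus the
#'    modified sCT (sCT classes overridden to the cohort CT means);
#' 5. for each patient and plan style, build and normalize a plan on the CT
#'    density volume, then recompute it with identical parameters on the
#'    modified sCT converted under the original and under the optimized
#'    curve;
#' 6. evaluate: 3%/3 mm local gamma (optimized curve versus CT) and D95
#'    coverage ratios under both curves.
#'
#' Any stage failure aborts with the stage name and the patient id.
#'
#' @param config a [study_config()].
#' @param keep_cohort also return the generated cohort volumes.
#' @param verbose log per-stage timings to the message stream.
#' @return An object of class `sct_study` with elements `class_stats`
#'   (cohort HU table), `mae` (per-patient MAE table), `dosimetry`
#'   (per-patient, per-style gamma and D95 ratios), `curves`, `cohort_stats`,
#'   `config`. When `config$out_dir` is set everything is also written to
#'   disk with provenance.
#' @export
run_study <- function(config = study_config(), keep_cohort = FALSE,
                      verbose = FALSE) {
  stopifnot(inherits(config, "study_config"))
  stage <- function(name, patient, expr) {
    t0 <- Sys.time()
    out <- tryCatch(expr, error = function(e)
      stopf("stage '%s' failed for patient %s: %s", name,
            if (is.null(patient)) "-" else patient, conditionMessage(e)))
    if (verbose)
      message(sprintf("[%s] patient %s: %.2f s", name,
                      if (is.null(patient)) "-" else patient,
                      as.numeric(Sys.time() - t0, units = "secs")))
    out
  }
  cohort <- stage("simulate", NULL,
                  generate_cohort(config$n_patients, config$base_spec,
                                  jitter = config$jitter, seed = config$seed,
                                  classes = config$classes))

  # --- segmentation and cohort HU statistics -------------------------------
  segs <- lapply(seq_along(cohort), function(i)
    stage("segment", i, segment_classes(cohort[[i]]$ct, config$scheme)))
  stats_list <- lapply(seq_along(cohort), function(i)
    stage("class_stats", i, class_hu_stats(cohort[[i]]$ct, segs[[i]])))
  cstats <- cohort_class_stats(stats_list)

  # --- calibration curves --------------------------------------------------
  curves <- list(
    original = build_original_curve(config$classes),
    optimized = derive_optimized_curve(cstats, classes = config$classes,
                                       keep_sct_bone = TRUE),
    ct = derive_optimized_curve(cstats, classes = config$classes,
                                keep_sct_bone = FALSE))
  curves$ct$provenance <- "ct"

  # --- HU agreement --------------------------------------------------------
  override_hu <- c(adipose = cstats$mean_hu[cstats$class == "adipose"],
                   soft_tissue = cstats$mean_hu[cstats$class == "soft_tissue"])
  mae_tab <- cohort_mae_table(cohort, override_hu, scheme = config$scheme)

  # --- planning and dosimetric evaluation ----------------------------------
  rows <- list()
  for (i in seq_along(cohort)) {
    p <- cohort[[i]]
    body <- p$structures$masks$body
    ptv <- p$structures$masks$ptv
    # planning CT: standard small-metal HU override (fiducials/calcifications)
    ct_plan <- override_metal_hu(p$ct, replacement_hu =
                                   cstats$mean_hu[cstats$class == "soft_tissue"])
    red_ct <- predict(curves$ct, ct_plan)
    sct_mod <- override_classes(p$sct, sct_class_masks(p$sct), override_hu)
    red_orig <- predict(curves$original, sct_mod)
    red_opt <- predict(curves$optimized, sct_mod)
    for (style in config$plan_styles) {
      plan <- stage(paste0("plan_", style), i,
                    make_plan(style, ptv, red_ct, body,
                              n_beams = config$n_beams[[style]],
                              prescription = config$prescription,
                              mu = config$mu, seed = p$seed + 2000000L))
      dose_ct <- stage(paste0("dose_", style), i, compute_dose(plan, red_ct, body))
      dose_orig <- compute_dose(plan, red_orig, body)
      dose_opt <- compute_dose(plan, red_opt, body)
      gam <- stage(paste0("evaluate_", style), i,
                   gamma_index(dose_ct, dose_opt, config$criteria,
                               prescription = config$prescription))
      rows[[length(rows) + 1L]] <- data.frame(
        patient = i, seed = p$seed, style = style,
        gamma_pass_optimized = gam$pass_rate,
        d95_ratio_optimized = d95_ratio(dose_opt, dose_ct, ptv),
        d95_ratio_original = d95_ratio(dose_orig, dose_ct, ptv),
        stringsAsFactors = FALSE)
    }
  }
  dosimetry <- do.call(rbind, rows)

  class_stats <- data.frame(
    class = cstats$class,
    ct_mean_hu = cstats$mean_hu,
    ct_sd_between = cstats$sd_between,
    sct_bulk_hu = classes_ordered(config$classes)$sct_bulk_hu,
    stringsAsFactors = FALSE)

  out <- structure(list(class_stats = class_stats, mae = mae_tab,
                        dosimetry = dosimetry, curves = curves,
                        cohort_stats = cstats, config = config,
                        cohort = if (keep_cohort) cohort),
                   class = "sct_study")
  if (!is.null(config$out_dir)) write_study(out, config$out_dir)
  out
}

study_summary_stats <- function(x) {
  do.call(rbind, lapply(split(x$dosimetry, x$dosimetry$style), function(d) {
    data.frame(style = d$style[1],
               gamma_mean = mean(d$gamma_pass_optimized),
               gamma_sd = stats::sd(d$gamma_pass_optimized),
               gamma_min = min(d$gamma_pass_optimized),
               gamma_max = max(d$gamma_pass_optimized),
               d95_opt_mean = mean(d$d95_ratio_optimized),
               d95_opt_sd = stats::sd(d$d95_ratio_optimized),
               d95_orig_mean = mean(d$d95_ratio_original),
               d95_orig_sd = stats::sd(d$d95_ratio_original),
               row.names = NULL)
  }))
}

#' @export
print.sct_study <- function(x, ...) {
  cat(sprintf("<sct_study> %d patients, seed %d\n", x$config$n_patients,
              x$config$seed))
  cat("\nCohort CT class statistics (HU):\n")
  print(transform(x$class_stats, ct_mean_hu = round(ct_mean_hu, 1),
                  ct_sd_between = round(ct_sd_between, 2)), row.names = FALSE)
  s <- attr(x$mae, "summary")
  tot <- s[s$metric %in% c("total_original", "total_modified"), ]
  cat(sprintf("\nTotal MAE: original %.1f +/- %.1f HU, modified %.1f +/- %.1f HU\n",
              tot$mean[1], tot$sd[1], tot$mean[2], tot$sd[2]))
  cat("\nDosimetry (optimized curve gamma, D95 ratios):\n")
  print(transform(study_summary_stats(x),
                  gamma_mean = round(gamma_mean, 2), gamma_sd = round(gamma_sd, 2),
                  gamma_min = round(gamma_min, 2), gamma_max = round(gamma_max, 2),
                  d95_opt_mean = round(d95_opt_mean, 2), d95_opt_sd = round(d95_opt_sd, 3),
                  d95_orig_mean = round(d95_orig_mean, 2), d95_orig_sd = round(d95_orig_sd, 3)),
        row.names = FALSE)
  invisible(x)
}

#' @export
summary.sct_study <- function(object, ...) {
  list(class_stats = object$class_stats,
       mae_summary = attr(object$mae, "summary"),
       dosimetry_summary = study_summary_stats(object))
}

#' Write a study report to disk
#'
#' Emits machine-readable CSV/JSON tables (class statistics, MAE, dosimetry),
#' the three calibration curves, the configuration, and a provenance file
#' with the configuration's MD5 hash.
#'
#' @param study an [run_study()] result.
#' @param dir output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(study$class_stats, file.path(dir, "class_stats.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(study$mae), file.path(dir, "mae_table.csv"),
                   row.names = FALSE)
  utils::write.csv(study$dosimetry, file.path(dir, "dosimetry.csv"),
                   row.names = FALSE)
  utils::write.csv(study_summary_stats(study), file.path(dir, "summary.csv"),
                   row.names = FALSE)
  for (nm in names(study$curves))
    write_calibration(study$curves[[nm]], file.path(dir, paste0("curve_", nm, ".csv")))
  cfg <- study$config
  cfg_json <- file.path(dir, "config.json")
  jsonlite::write_json(list(n_patients = cfg$n_patients, seed = cfg$seed,
                            jitter = cfg$jitter,
                            shape = cfg$base_spec$shape,
                            spacing = cfg$base_spec$spacing,
                            artifacts = cfg$base_spec$artifacts,
                            plan_styles = cfg$plan_styles,
                            prescription = cfg$prescription,
                            n_beams = as.list(cfg$n_beams), mu = cfg$mu,
                            gamma = unclass(cfg$criteria),
                            boundaries = cfg$scheme$boundaries,
                            opening_radius = cfg$scheme$opening_radius),
                       cfg_json, auto_unbox = TRUE, digits = NA)
  md5 <- unname(tools::md5sum(cfg_json))
  jsonlite::write_json(list(config_md5 = md5,
                            files = list.files(dir)),
                       file.path(dir, "provenance.json"), auto_unbox = TRUE)
  invisible(dir)
}
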