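#' Run the full ROI-vs-VOI noise study on a cohort
#'
#' Orchestrates the complete study design per scan — airway segmentation,
#' carina-ridge detection, height selection and the 27-position jittered
#' ROI/VOI measurement — then pools all kept measurements across scans,
#' performs Bland-Altman analysis of each method against the per-scan ground
#' truth, compares the two methods (Levene on variability, Wilcoxon
#' signed-rank on bias), and accounts for every excluded position. The
#' headline summary is the variability reduction
#' `100 * (1 - loa_distance_sphere / loa_distance_circle)` in percent.
#'
#' @param cohort A list of scans: `ct_phantom` objects (from
#'   [generate_cohort()]), or lists with elements `volume` (a
#'   [ct_volume()]) and `seed_voxel`.
#' @param area_cm2 ROI area defining the shared shape radius.
#' @param hu_threshold Air threshold for segmentation, HU.
#' @param heights_cm Candidate measurement heights above the carina, cm.
#' @param pairing Pairing unit for the Wilcoxon bias test:
#'   `"position"` (default; each kept jitter position is a pair) or
#'   `"scan"` (per-scan mean differences, one pair per scan).
#' @param cranial Cranial direction flag passed to [detect_carina()].
#' @return A `noise_study` object; see [glance.noise_study()],
#'   [tidy.noise_study()] and [autoplot.noise_study()].
#' @details Scans whose segmentation, landmark detection or measurement
#'   fails are skipped with a logged reason (in `$failed_scans`), not fatal.
#'   At least 2 scans must succeed.
#' @export
run_study <- function(cohort, area_cm2 = 1.0, hu_threshold = -500,
                      heights_cm = c(1.0, 1.5, 2.0),
                      pairing = c("position", "scan"), cranial = "+k") {
  pairing <- match.arg(pairing)
  if (!is.list(cohort) || length(cohort) < 2L) {
    abort("`cohort` must be a list of at least 2 scans.",
          class = "voinoise_invalid_parameter")
  }
  ids <- names(cohort)
  if (is.null(ids)) ids <- sprintf("scan%03d", seq_along(cohort))
  scans <- list()
  failures <- list()
  for (s in seq_along(cohort)) {
    el <- cohort[[s]]
    vol <- el$volume
    seed <- el$seed_voxel %||% el$seed
    res <- tryCatch({
      mask <- segment_airway(vol, seed, hu_threshold)
      lm <- detect_carina(mask, cranial)
      evaluate_scan(vol, mask, lm, area_cm2 = area_cm2,
                    heights_cm = heights_cm, scan_id = ids[s])
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures[[length(failures) + 1L]] <-
        tibble(scan_id = ids[s], reason = conditionMessage(res))
    } else {
      scans[[length(scans) + 1L]] <- res
    }
  }
  if (length(scans) < 2L) {
    abort("Fewer than 2 scans produced valid measurements.",
          class = "voinoise_scan_failure")
  }
  measurements <- dplyr::bind_rows(lapply(scans, `[[`, "measurements"))
  scan_table <- dplyr::bind_rows(lapply(scans, function(x) {
    tibble(scan_id = x$scan_id, height_cm = x$height_cm,
           rejections = sum(x$measurements$excluded[x$measurements$shape == "circle"]),
           true_noise_hu = x$true_noise_hu)
  }))
  kept <- measurements[!measurements$excluded, ]
  kc <- kept[kept$shape == "circle", ]
  ks <- kept[kept$shape == "sphere", ]
  dc <- kc$noise_hu - kc$true_noise_hu
  ds <- ks$noise_hu - ks$true_noise_hu
  ba_circle <- bland_altman(kc$noise_hu, kc$true_noise_hu)
  ba_sphere <- bland_altman(ks$noise_hu, ks$true_noise_hu)
  if (pairing == "scan") {
    agg <- function(tab) {
      d <- tab$noise_hu - tab$true_noise_hu
      tapply(d, tab$scan_id, mean)
    }
    mc <- agg(kc); ms <- agg(ks)
    ms <- ms[names(mc)]
    comparison <- structure(list(levene = levene_variability_test(dc, ds),
                                 wilcoxon = wilcoxon_bias_test(mc, ms)),
                            class = "method_comparison")
  } else {
    comparison <- compare_methods(dc, ds)
  }
  n_scans_ok <- nrow(scan_table)
  positions_total <- 27L * n_scans_ok
  positions_excluded <- sum(measurements$excluded[measurements$shape == "circle"])
  structure(list(
    measurements = measurements,
    scans = scan_table,
    failed_scans = if (length(failures)) dplyr::bind_rows(failures)
                   else tibble(scan_id = character(), reason = character()),
    agreement = list(circle = ba_circle, sphere = ba_sphere),
    comparison = comparison,
    exclusion = list(positions_total = positions_total,
                     positions_excluded = positions_excluded,
                     values_total = 2L * positions_total,
                     values_excluded = 2L * positions_excluded,
                     rate_pct = 100 * positions_excluded / positions_total),
    reduction_pct = 100 * (1 - ba_sphere$loa_distance / ba_circle$loa_distance),
    settings = list(area_cm2 = area_cm2, hu_threshold = hu_threshold,
                    heights_cm = heights_cm, pairing = pairing)),
    class = "noise_study")
}

#' @export
print.noise_study <- function(x, ...) {
  cat(sprintf("<noise_study> %d scans (%d failed), %d/%d positions excluded (%.1f%%)\n",
              nrow(x$scans), nrow(x$failed_scans),
              x$exclusion$positions_excluded, x$exclusion$positions_total,
              x$exclusion$rate_pct))
  cat(sprintf("  circle: bias %+.2f HU, LoA distance %.2f HU\n",
              x$agreement$circle$bias, x$agreement$circle$loa_distance))
  cat(sprintf("  sphere: bias %+.2f HU, LoA distance %.2f HU\n",
              x$agreement$sphere$bias, x$agreement$sphere$loa_distance))
  cat(sprintf("  variability reduction %.1f%% (Levene p = %.3g; Wilcoxon p = %.3g)\n",
              x$reduction_pct, x$comparison$levene$p.value,
              x$comparison$wilcoxon$p.value))
  invisible(x)
}

#' One-row summary of a noise study
#'
#' @param x A `noise_study`.
#' @param ... Unused.
#' @return A one-row tibble with the pooled agreement statistics per shape,
#'   the test p-values, exclusion accounting and the variability-reduction
#'   percentage.
#' @method glance noise_study
#' @export
glance.noise_study <- function(x, ...) {
  tibble(n_scans = nrow(x$scans),
         n_failed = nrow(x$failed_scans),
         bias_circle = x$agreement$circle$bias,
         bias_sphere = x$agreement$sphere$bias,
         loa_distance_circle = x$agreement$circle$loa_distance,
         loa_distance_sphere = x$agreement$sphere$loa_distance,
         reduction_pct = x$reduction_pct,
         levene_p = x$comparison$levene$p.value,
         wilcoxon_p = x$comparison$wilcoxon$p.value,
         positions_total = x$exclusion$positions_total,
         positions_excluded = x$exclusion$positions_excluded,
         exclusion_rate_pct = x$exclusion$rate_pct)
}

#' Per-measurement table of a noise study
#'
#' @param x A `noise_study`.
#' @param ... Unused.
#' @return The pooled measurement tibble (one row per scan x position x
#'   shape, kept and excluded).
#' @method tidy noise_study
#' @export
tidy.noise_study <- function(x, ...) x$measurements

#' Export a study report to CSV and JSON
#'
#' Writes `measurements.csv` (the full per-position table) and
#' `report.json` (agreement, comparison, exclusion accounting and settings)
#' into a directory.
#'
#' @param study A `noise_study`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_study_report <- function(study, dir) {
  stopifnot(inherits(study, "noise_study"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(study$measurements, file.path(dir, "measurements.csv"))
  report <- list(
    scans = study$scans,
    failed_scans = study$failed_scans,
    agreement = list(circle = glance.bland_altman(study$agreement$circle),
                     sphere = glance.bland_altman(study$agreement$sphere)),
    comparison = list(
      levene = list(statistic = unname(study$comparison$levene$statistic),
                    p = study$comparison$levene$p.value),
      wilcoxon = list(statistic = unname(study$comparison$wilcoxon$statistic),
                      p = study$comparison$wilcoxon$p.value)),
    exclusion = study$exclusion,
    reduction_pct = study$reduction_pct,
    settings = study$settings)
  jsonlite::write_json(report, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(dir)
}
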