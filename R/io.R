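#' End-to-end simulated-cohort analysis
#'
#' Simulates the default (or a supplied) cohort, runs the stride pipeline
#' per cell, computes descriptive summaries per group, runs the full
#' comparison battery (Kruskal-Wallis on medians and Levene on variability,
#' with and without 1.5-IQR outlier removal for leg gap) and tabulates the
#' detection accuracy of each criterion.
#'
#' The five criteria mirror the study's analysis variants: leg-gap median
#' and leg-gap variability are assessed after outlier removal, their union
#' flags a stride type if either does, and the cadence criteria use the raw
#' cadence series.
#'
#' @param params Cohort parameter grid (see [default_cohort_params()]).
#' @param seed Master seed for the simulation.
#' @param alpha Significance level for every test.
#' @param config,magnet,sensor,geom Simulation and physical-model settings.
#' @param min_separation,prominence_fraction Peak-detection settings.
#' @return A list of class `gait_analysis`: `measurements`,
#'   `descriptives` (per group), `comparisons` (named list of comparison
#'   tables: `gap_kw`, `gap_kw_no_outliers`, `gap_levene`,
#'   `gap_levene_no_outliers`, `cadence_kw`, `cadence_levene`),
#'   `detection` (per-criterion accuracy tibble) and `cells`.
#' @export
run_gait_analysis <- function(params = default_cohort_params(), seed = 1L,
                              alpha = 0.05, config = simulation_config(),
                              magnet = ring_magnet(), sensor = hall_sensor(),
                              geom = mount_geometry(), min_separation = 0.8,
                              prominence_fraction = 0.25) {
  cohort <- make_cohort(params, config, magnet, sensor, geom, seed = seed,
                        min_separation = min_separation,
                        prominence_fraction = prominence_fraction)
  meas <- cohort$measurements

  desc <- do.call(rbind, lapply(
    split(meas, list(meas$subject, meas$stride_type, meas$measure),
          drop = TRUE),
    function(d) tibble::tibble(subject = d$subject[1],
                               stride_type = d$stride_type[1],
                               measure = d$measure[1],
                               describe_group(d$value, alpha = alpha))))
  desc <- desc[order(desc$measure, desc$subject,
                     match(desc$stride_type, stride_types)), ]

  comparisons <- list(
    gap_kw = compare_all_subjects(meas, "leg_gap", "kruskal_wallis",
                                  alpha, "keep"),
    gap_kw_no_outliers = compare_all_subjects(meas, "leg_gap",
                                              "kruskal_wallis", alpha,
                                              "remove"),
    gap_levene = compare_all_subjects(meas, "leg_gap", "levene", alpha,
                                      "keep"),
    gap_levene_no_outliers = compare_all_subjects(meas, "leg_gap", "levene",
                                                  alpha, "remove"),
    cadence_kw = compare_all_subjects(meas, "cadence", "kruskal_wallis",
                                      alpha, "keep"),
    cadence_levene = compare_all_subjects(meas, "cadence", "levene", alpha,
                                          "keep"))

  pairwise_p <- function(tbl) {
    d <- tbl[tbl$stride_type != "All", ]
    d <- d[order(d$subject, match(d$stride_type, stride_types)), ]
    d$p
  }
  detection <- rbind(
    tabulate_detection(pairwise_p(comparisons$gap_kw_no_outliers), alpha,
                       "gap_median"),
    tabulate_detection(pairwise_p(comparisons$gap_levene_no_outliers),
                       alpha, "gap_variability"),
    tabulate_detection(pairwise_p(comparisons$gap_kw_no_outliers), alpha,
                       "union",
                       p2 = pairwise_p(comparisons$gap_levene_no_outliers)),
    tabulate_detection(pairwise_p(comparisons$cadence_kw), alpha,
                       "cadence_median"),
    tabulate_detection(pairwise_p(comparisons$cadence_levene), alpha,
                       "cadence_variability"))

  structure(list(measurements = meas, descriptives = desc,
                 comparisons = comparisons, detection = detection,
                 cells = cohort$cells, seed = seed, alpha = alpha),
            class = "gait_analysis")
}

#' @export
print.gait_analysis <- function(x, ...) {
  cat(sprintf("<gait_analysis> %d measurements, seed %d, alpha %.3g\n",
              nrow(x$measurements), x$seed, x$alpha))
  print(x$detection)
  invisible(x)
}

#' Write a comparison table as CSV
#'
#' Mirrors the column structure of the study's detection tables: subject,
#' stride type, test, statistic, degrees of freedom, p-value, significance
#' stars.
#'
#' @param tbl A comparison table from [compare_all_subjects()].
#' @param path Output CSV path.
#' @export
write_comparison_csv <- function(tbl, path) {
  d <- data.frame(subject = tbl$subject, measure = tbl$measure,
                  stride_type = tbl$stride_type, test = tbl$test,
                  statistic = round(tbl$statistic, 12), df = tbl$df,
                  p = round(tbl$p, 12), stars = tbl$stars)
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write the per-criterion detection summary as JSON
#'
#' @param analysis A `gait_analysis` from [run_gait_analysis()] (or any
#'   detection tibble from [tabulate_detection()] rows).
#' @param path Output JSON path.
#' @export
write_detection_json <- function(analysis, path) {
  det <- if (inherits(analysis, "gait_analysis")) analysis$detection
         else analysis
  out <- stats::setNames(lapply(seq_len(nrow(det)), function(i)
    list(n_comparisons = det$n_comparisons[i],
         n_significant = det$n_significant[i],
         accuracy_pct = det$accuracy_pct[i])), det$criterion)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
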