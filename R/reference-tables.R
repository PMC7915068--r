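#' Published reference tables of the original wearable study
#'
#' Digitized copies of the descriptive-statistics and hypothesis-test tables
#' reported for the original four-subject, five-stride-type cohort, shipped
#' with the package as plain-text CSVs. They serve two purposes: the
#' descriptive rows parameterize the default synthetic cohort
#' ([default_cohort_params()]), and the test rows let the
#' significance-tabulation and shape-classification logic be checked
#' against the published headline counts without access to the raw logged
#' traces.
#'
#' @return `published_descriptives()`: a tibble with one row per measure x
#'   subject x stride type (`n`, `mean`, `sd`, `iqr`, `max`, `min`,
#'   `skewness`, `kurtosis`, `normal`). `published_test_results()`: a tibble
#'   of reported test outcomes (`table`, `measure`, `test`,
#'   `outliers_removed`, `subject`, `stride_type`, `statistic`, `df`, `p`),
#'   where `table` identifies the analysis variant (e.g. `gap_kw`,
#'   `gap_levene_no_outliers`, `cadence_kw`) and `stride_type = "All"` marks
#'   the five-group omnibus rows.
#' @export
published_descriptives <- function() {
  path <- system.file("extdata", "reference_descriptives.csv",
                      package = "hallgait", mustWork = TRUE)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  d$normal <- d$normal == "Y"
  tibble::as_tibble(d)
}

#' @rdname published_descriptives
#' @export
published_test_results <- function() {
  path <- system.file("extdata", "reference_tests.csv",
                      package = "hallgait", mustWork = TRUE)
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Distribution-shape counts for a set of descriptive summaries
#'
#' Classifies each group's skewness ([classify_skewness()]) and counts the
#' shape categories used to characterize the cohort: highly skewed
#' (`|g1| > 1`), moderately skewed, approximately symmetric, negatively
#' skewed, and more peaked than the normal distribution (non-excess
#' kurtosis above 3).
#'
#' @param desc A descriptive table with columns `skewness` and `kurtosis`
#'   (e.g. a subset of [published_descriptives()], or stacked
#'   [describe_group()] rows).
#' @return A one-row [tibble::tibble] with `n_groups`, `n_high_skew`,
#'   `n_moderate_skew`, `n_symmetric`, `n_negative_skew`,
#'   `n_kurtosis_above_normal`.
#' @export
shape_counts <- function(desc) {
  stopifnot(is.data.frame(desc),
            all(c("skewness", "kurtosis") %in% names(desc)))
  cls <- classify_skewness(desc$skewness)
  tibble::tibble(
    n_groups = nrow(desc),
    n_high_skew = sum(cls == "high"),
    n_moderate_skew = sum(cls == "moderate"),
    n_symmetric = sum(cls == "approximately_symmetric"),
    n_negative_skew = sum(desc$skewness < 0),
    n_kurtosis_above_normal = sum(desc$kurtosis > 3))
}

#' Detection summaries recomputed from the published test tables
#'
#' Feeds the reported pairwise p-values through [tabulate_detection()] for
#' each detection criterion: leg-gap median (Kruskal-Wallis, outliers
#' removed), leg-gap variability (Levene, outliers removed), their union,
#' cadence median (Kruskal-Wallis) and cadence variability (Levene).
#'
#' @param alpha Significance level.
#' @return A [tibble::tibble] with one row per criterion.
#' @export
published_detection_summary <- function(alpha = 0.05) {
  tests <- published_test_results()
  pairwise <- function(tbl) {
    d <- tests[tests$table == tbl & tests$stride_type != "All", ]
    # fixed cell order: subject, then stride type
    d <- d[order(d$subject, match(d$stride_type, stride_types)), ]
    d$p
  }
  rbind(
    tabulate_detection(pairwise("gap_kw_no_outliers"), alpha,
                       "gap_median"),
    tabulate_detection(pairwise("gap_levene_no_outliers"), alpha,
                       "gap_variability"),
    tabulate_detection(pairwise("gap_kw_no_outliers"), alpha, "union",
                       p2 = pairwise("gap_levene_no_outliers")),
    tabulate_detection(pairwise("cadence_kw"), alpha, "cadence_median"),
    tabulate_detection(pairwise("cadence_levene"), alpha,
                       "cadence_variability"))
}
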