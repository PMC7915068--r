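#' Stride types monitored by the wearable
#'
#' Normal gait, two abnormal types (fast and slow walking) and two irregular
#' types (right and left antalgic gait, i.e. limps simulated by walking with
#' one shoe off).
#'
#' @export
stride_types <- c("Normal", "Fast", "Slow", "RightAntalgic", "LeftAntalgic")

star_label <- function(p) {
  ifelse(is.na(p), "",
         ifelse(p < 0.001, "***", ifelse(p < 0.01, "**",
                                         ifelse(p < 0.05, "*", ""))))
}

comparison_row <- function(test, statistic, df, p, alpha) {
  tibble::tibble(test = test, statistic = statistic, df = df, p = p,
                 significant = !is.na(p) & p < alpha, alpha = alpha,
                 stars = star_label(p))
}

# Moment (biased) estimators: g1 skewness and non-excess kurtosis b2
# (normal => ~3), the conventions used in the study's summary tables.
moment_skewness <- function(x) e1071::skewness(x, type = 1)
moment_kurtosis <- function(x) e1071::kurtosis(x, type = 1) + 3

# Quartiles by the midpoint-interpolation convention (R type 5), matching
# the default of the commercial numerical environment the original analysis
# used. Borderline outlier membership can shift under other conventions.
quartiles5 <- function(x) unname(stats::quantile(x, c(0.25, 0.75), type = 5))

#' Descriptive summary of one gait measurement group
#'
#' Sample size, location, spread (SD, IQR, max, min), moment skewness `g1`,
#' non-excess kurtosis (normal reference value 3) and a Lilliefors normality
#' flag at level `alpha`.
#'
#' @param values Numeric measurements (leg gap in cm or cadence in
#'   steps/min) for one subject and stride type; at least 3, at least 4 for
#'   the normality flag.
#' @param alpha Significance level of the normality screen.
#' @param lilliefors_method Passed to [lilliefors_test()].
#' @return A one-row [tibble::tibble] with columns `n`, `mean`, `sd`, `iqr`,
#'   `max`, `min`, `skewness`, `kurtosis`, `normal`.
#' @export
describe_group <- function(values, alpha = 0.05,
                           lilliefors_method = c("approx", "mc")) {
  stopifnot(is.numeric(values))
  values <- values[!is.na(values)]
  if (length(values) < 3)
    stop("describe_group: need at least 3 values", call. = FALSE)
  q <- quartiles5(values)
  constant <- stats::sd(values) == 0
  normal <- if (constant || length(values) < 4) FALSE else
    !lilliefors_test(values, alpha = alpha,
                     method = match.arg(lilliefors_method))$significant
  tibble::tibble(
    n = length(values), mean = mean(values), sd = stats::sd(values),
    iqr = q[2] - q[1], max = max(values), min = min(values),
    skewness = if (constant) NA_real_ else moment_skewness(values),
    kurtosis = if (constant) NA_real_ else moment_kurtosis(values),
    normal = normal)
}

#' Classify a skewness value
#'
#' The conventional bands: `|g1| > 1` highly skewed, `0.5 < |g1| <= 1`
#' moderately skewed, otherwise approximately symmetric.
#'
#' @param g1 Skewness value(s).
#' @return Character vector in
#'   `{"approximately_symmetric", "moderate", "high"}`.
#' @export
classify_skewness <- function(g1) {
  stopifnot(is.numeric(g1), all(is.finite(g1)))
  ifelse(abs(g1) > 1, "high",
         ifelse(abs(g1) > 0.5, "moderate", "approximately_symmetric"))
}

# Lilliefors KS distance: empirical CDF against a normal with mean/sd
# estimated from the sample.
lilliefors_D <- function(x) {
  n <- length(x)
  z <- stats::pnorm(sort(x), mean(x), stats::sd(x))
  max(pmax(seq_len(n) / n - z, z - (seq_len(n) - 1) / n))
}

#' Lilliefors test for normality
#'
#' Kolmogorov-Smirnov-type test with the normal parameters estimated from
#' the sample. `method = "approx"` uses the standard Dallal-Wilkinson
#' p-value approximation; `method = "mc"` estimates the p-value from a
#' seeded Monte-Carlo null (draws standard-normal samples of the same size
#' and compares their distances).
#'
#' @param values Numeric sample, n >= 4.
#' @param alpha Significance level; `significant` means normality rejected.
#' @param method `"approx"` or `"mc"`.
#' @param B Monte-Carlo replicates for `method = "mc"`.
#' @param seed Seed for the Monte-Carlo null (ignored for `"approx"`).
#' @return A one-row comparison table (`test`, `statistic` = D, `df` = n,
#'   `p`, `significant`, `alpha`, `stars`).
#' @export
lilliefors_test <- function(values, alpha = 0.05,
                            method = c("approx", "mc"), B = 10000,
                            seed = 1L) {
  method <- match.arg(method)
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 4)
    stop("lilliefors_test: need at least 4 values", call. = FALSE)
  if (stats::sd(values) == 0)  # degenerate: certainly not normal
    return(comparison_row("lilliefors", NA_real_, n, 0, alpha))
  D <- lilliefors_D(values)
  p <- if (method == "approx") {
    nortest::lillie.test(values)$p.value
  } else {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                        globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    D0 <- vapply(seq_len(B),
                 function(i) lilliefors_D(stats::rnorm(n)), numeric(1))
    (1 + sum(D0 >= D)) / (B + 1)
  }
  comparison_row("lilliefors", D, n, p, alpha)
}

#' Kruskal-Wallis comparison of gait groups
#'
#' Rank-based k-group test on medians (tie-corrected H, chi-square reference
#' with k - 1 degrees of freedom); with two groups it is equivalent to the
#' Mann-Whitney test. Used to compare leg gap or cadence of an abnormal or
#' irregular stride type against normal gait.
#'
#' @param groups Named list of numeric vectors (>= 2 groups, each n >= 3).
#' @param alpha Significance level.
#' @return A one-row comparison table.
#' @export
kruskal_wallis <- function(groups, alpha = 0.05) {
  stopifnot(is.list(groups), length(groups) >= 2)
  if (any(vapply(groups, length, 1L) < 3))
    stop("kruskal_wallis: each group needs n >= 3", call. = FALSE)
  pooled <- unlist(groups, use.names = FALSE)
  k <- length(groups)
  if (length(unique(pooled)) == 1)  # all tied: no evidence of difference
    return(comparison_row("kruskal_wallis", 0, k - 1, 1, alpha))
  g <- factor(rep(seq_along(groups), lengths(groups)))
  kt <- stats::kruskal.test(pooled, g)
  comparison_row("kruskal_wallis", unname(kt$statistic),
                 unname(kt$parameter), kt$p.value, alpha)
}

#' Levene's test for equality of variances
#'
#' Classic (mean-centered) Levene: a one-way ANOVA on absolute deviations
#' from each group's center. Robust to non-normality, which is why it is
#' used for the leg-gap and cadence variability comparisons. `center` can
#' be set to `median` for the Brown-Forsythe variant.
#'
#' @param groups Named list of numeric vectors (>= 2 groups, each n >= 3).
#' @param alpha Significance level.
#' @param center Function giving each group's center (default `mean`).
#' @return A one-row comparison table with `statistic` = F and `df` = the
#'   numerator degrees of freedom (k - 1); denominator df is N - k.
#' @export
levene_test <- function(groups, alpha = 0.05, center = mean) {
  stopifnot(is.list(groups), length(groups) >= 2)
  if (any(vapply(groups, length, 1L) < 3))
    stop("levene_test: each group needs n >= 3", call. = FALSE)
  adev <- lapply(groups, function(v) abs(v - center(v)))
  y <- unlist(adev, use.names = FALSE)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  if (all(y == 0))  # no within-group spread anywhere: degenerate
    return(comparison_row("levene", 0, length(groups) - 1, 1, alpha))
  a <- stats::anova(stats::aov(y ~ g))
  comparison_row("levene", a[["F value"]][1], a[["Df"]][1],
                 a[["Pr(>F)"]][1], alpha)
}

#' Remove 1.5-IQR outliers from a measurement group
#'
#' Drops values below `Q1 - k*IQR` or above `Q3 + k*IQR` (quartiles by the
#' midpoint-interpolation convention), applied exactly once. With fewer
#' than 4 values the input is returned unchanged with a warning.
#'
#' @param values Numeric vector.
#' @param k Fence multiplier (1.5 is the conventional rule).
#' @return The filtered vector, order preserved.
#' @export
remove_outliers <- function(values, k = 1.5) {
  stopifnot(is.numeric(values))
  if (length(values) < 4) {
    warning("remove_outliers: fewer than 4 values, returned unchanged")
    return(values)
  }
  q <- quartiles5(values)
  iqr <- q[2] - q[1]
  values[values >= q[1] - k * iqr & values <= q[2] + k * iqr]
}

#' Compare each non-normal stride type to normal gait for one subject
#'
#' Runs the chosen test pairwise (Fast, Slow, RightAntalgic, LeftAntalgic
#' each against Normal) plus a five-group omnibus comparison. The optional
#' outlier policy applies the 1.5-IQR rule once per group before testing.
#'
#' @param measurements Long table with columns `subject`, `stride_type`,
#'   `measure`, `value` (as produced by [make_cohort()]).
#' @param subject Subject label to analyze.
#' @param measure `"leg_gap"` or `"cadence"`.
#' @param test `"kruskal_wallis"` (medians) or `"levene"` (variability).
#' @param alpha Significance level.
#' @param outlier_policy `"keep"` or `"remove"` (per-group 1.5-IQR).
#' @return A comparison table with one row per stride type plus an `"All"`
#'   omnibus row; stride types absent from the data yield `NA` rows.
#' @export
compare_to_normal <- function(measurements, subject, measure = "leg_gap",
                              test = c("kruskal_wallis", "levene"),
                              alpha = 0.05,
                              outlier_policy = c("keep", "remove")) {
  test <- match.arg(test)
  outlier_policy <- match.arg(outlier_policy)
  stopifnot(is.data.frame(measurements),
            all(c("subject", "stride_type", "measure", "value") %in%
                  names(measurements)))
  d <- measurements[measurements$subject == subject &
                      measurements$measure == measure &
                      !is.na(measurements$value), ]
  groups <- split(d$value, factor(d$stride_type, levels = stride_types))
  if (outlier_policy == "remove")
    groups <- lapply(groups, function(v) if (length(v) >= 4)
      remove_outliers(v) else v)
  test_fun <- if (test == "kruskal_wallis") kruskal_wallis else levene_test
  na_row <- comparison_row(test, NA_real_, NA_real_, NA_real_, alpha)

  one <- function(type) {
    if (length(groups[[type]]) < 3 || length(groups[["Normal"]]) < 3)
      return(na_row)
    test_fun(groups[c("Normal", type)], alpha = alpha)
  }
  others <- setdiff(stride_types, "Normal")
  rows <- do.call(rbind, lapply(others, one))
  present <- groups[vapply(groups, length, 1L) >= 3]
  omnibus <- if (length(present) == length(stride_types))
    test_fun(present, alpha = alpha) else na_row
  out <- rbind(rows, omnibus)
  tibble::tibble(subject = subject, measure = measure,
                 stride_type = c(others, "All"), out)
}

#' Compare all subjects' stride types to their normal gait
#'
#' @inheritParams compare_to_normal
#' @return Row-bound [compare_to_normal()] results over every subject in
#'   `measurements`.
#' @export
compare_all_subjects <- function(measurements, measure = "leg_gap",
                                 test = c("kruskal_wallis", "levene"),
                                 alpha = 0.05,
                                 outlier_policy = c("keep", "remove")) {
  subjects <- unique(measurements$subject)
  do.call(rbind, lapply(subjects, function(s)
    compare_to_normal(measurements, s, measure = measure, test = test,
                      alpha = alpha, outlier_policy = outlier_policy)))
}

#' Tabulate detection accuracy over pairwise comparisons
#'
#' Counts how many of the pairwise (stride type vs normal) comparisons were
#' significant at level `alpha` and expresses that as a rounded percentage
#' -- the detection accuracy of the criterion. For `criterion = "union"` a
#' comparison counts if it is significant under *either* of the two supplied
#' p-value sets (location or variability).
#'
#' @param p Numeric vector (or matrix) of pairwise p-values, one per
#'   subject x non-normal stride type cell (16 for a 4-subject cohort).
#' @param alpha Significance level.
#' @param criterion One of `"gap_median"`, `"gap_variability"`, `"union"`,
#'   `"cadence_median"`, `"cadence_variability"`.
#' @param p2 Second p-value set, required for `"union"`; must match `p` in
#'   length and cell order.
#' @return A one-row [tibble::tibble]: `criterion`, `n_comparisons`,
#'   `n_significant`, `accuracy_pct`.
#' @export
tabulate_detection <- function(p, alpha = 0.05,
                               criterion = c("gap_median", "gap_variability",
                                             "union", "cadence_median",
                                             "cadence_variability"),
                               p2 = NULL) {
  criterion <- match.arg(criterion)
  p <- as.vector(p)
  stopifnot(is.numeric(p), length(p) >= 1, all(is.na(p) | (p >= 0 & p <= 1)))
  sig <- !is.na(p) & p < alpha
  if (criterion == "union") {
    if (is.null(p2) || length(as.vector(p2)) != length(p))
      stop("tabulate_detection: 'union' needs p2 matching p", call. = FALSE)
    p2 <- as.vector(p2)
    sig <- sig | (!is.na(p2) & p2 < alpha)
  }
  tibble::tibble(criterion = criterion, n_comparisons = length(p),
                 n_significant = sum(sig),
                 accuracy_pct = round(100 * sum(sig) / length(p)))
}
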