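test_that("descriptive summaries use moment estimators and type-5 quartiles", {
  d <- describe_group(c(1, 2, 3, 4, 5))
  expect_equal(d$mean, 3)
  expect_equal(d$min, 1)
  expect_equal(d$max, 5)
  expect_equal(d$skewness, 0)
  expect_equal(d$iqr, 4.25 - 1.75)  # midpoint-interpolation quartiles
  expect_error(describe_group(c(1, 2)), "at least 3")
})

test_that("moment skewness and kurtosis are recovered from simulation", {
  set.seed(11)
  x <- rskewnorm(5000, mean = 10, sd = 2, skew = -0.9)
  expect_equal(describe_group(x)$skewness, -0.9, tolerance = 0.15)
  y <- rnorm(50)
  expect_equal(describe_group(y)$kurtosis, 3, tolerance = 1)
})

test_that("skewness classification uses the 0.5 and 1 bands", {
  expect_equal(classify_skewness(0.22), "approximately_symmetric")
  expect_equal(classify_skewness(-1.60), "high")
  expect_equal(classify_skewness(-0.67), "moderate")
  expect_equal(classify_skewness(c(0.5, -1, 1.01)),
               c("approximately_symmetric", "moderate", "high"))
})

test_that("Lilliefors test rejects non-normal and controls type I error", {
  set.seed(3)
  u <- runif(500)
  expect_true(lilliefors_test(u)$significant)
  expect_true(lilliefors_test(u, method = "mc", B = 500)$significant)
  # type-I calibration of the default p-value approximation
  set.seed(4)
  rej <- vapply(1:1000,
                function(i) lilliefors_test(rnorm(50))$significant,
                logical(1))
  expect_lt(abs(mean(rej) - 0.05), 0.02)
  expect_error(lilliefors_test(c(1, 2, 3)), "at least 4")
  expect_true(lilliefors_test(rep(1, 10))$significant)  # degenerate
})

test_that("Monte-Carlo and approximate Lilliefors p-values agree", {
  set.seed(9)
  x <- rnorm(40, 100, 5)
  p_ap <- lilliefors_test(x, method = "approx")$p
  p_mc <- lilliefors_test(x, method = "mc", B = 4000, seed = 2)$p
  expect_equal(p_mc, p_ap, tolerance = 0.08)
})

test_that("Kruskal-Wallis H matches the rank-formula oracle and kruskal.test", {
  expect_equal(kruskal_wallis(list(a = c(1, 2, 3), b = c(4, 5, 6)))$statistic,
               3.857, tolerance = 1e-3)
  set.seed(21)
  for (i in 1:20) {
    k <- sample(2:4, 1)
    groups <- lapply(seq_len(k), function(j)
      sample(1:10, sample(3:8, 1), replace = TRUE))  # ties included
    res <- kruskal_wallis(groups)
    expect_equal(res$statistic, kw_H_oracle(groups), tolerance = 1e-10)
    expect_equal(res$df, k - 1)
    expect_equal(res$p, stats::pchisq(res$statistic, k - 1,
                                      lower.tail = FALSE))
  }
})

test_that("Kruskal-Wallis is rank-based and handles degenerate input", {
  g1 <- c(1.2, 3.4, 2.2, 5.0)
  g2 <- c(2.1, 4.4, 6.3)
  h_raw <- kruskal_wallis(list(g1, g2))$statistic
  h_tr <- kruskal_wallis(list(exp(g1), exp(g2)))$statistic
  expect_equal(h_raw, h_tr)
  same <- kruskal_wallis(list(c(1, 1, 1), c(1, 1, 1)))
  expect_equal(same$statistic, 0)
  expect_equal(same$p, 1)
  ident <- kruskal_wallis(list(c(1, 2, 3), c(1, 2, 3)))
  expect_equal(ident$statistic, 0, tolerance = 1e-12)
})

test_that("exact permutation null agrees with the chi-square p at small n", {
  g1 <- c(1, 2, 3); g2 <- c(4, 5, 6)
  pooled <- c(g1, g2)
  combs <- utils::combn(6, 3)
  h_obs <- kw_H_oracle(list(g1, g2))
  h_all <- apply(combs, 2, function(idx)
    kw_H_oracle(list(pooled[idx], pooled[-idx])))
  expect_equal(kruskal_wallis(list(g1, g2))$statistic, h_obs)
  p_exact <- mean(h_all >= h_obs - 1e-12)
  expect_equal(p_exact, 0.1, tolerance = 1e-9)  # 2/20 extreme assignments
})

test_that("Levene F equals the brute-force oracle and car's mean-centred test", {
  groups <- list(a = c(-1, 1.2, -0.8, 1, -1.1, 0.9),
                 b = c(-5, 4.6, -5.2, 5, -4.8, 5.1))
  res <- levene_test(groups)
  expect_equal(res$statistic, levene_F_oracle(groups), tolerance = 1e-10)
  set.seed(31)
  for (i in 1:10) {
    g <- list(rnorm(8, sd = 1), rnorm(6, sd = 3), rnorm(7, sd = 2))
    res <- levene_test(g)
    expect_equal(res$statistic, levene_F_oracle(g), tolerance = 1e-9)
    y <- unlist(g)
    f <- factor(rep(seq_along(g), lengths(g)))
    ct <- car::leveneTest(y, f, center = mean)
    expect_equal(res$statistic, ct[["F value"]][1], tolerance = 1e-9)
    expect_equal(res$p, ct[["Pr(>F)"]][1], tolerance = 1e-9)
  }
})

test_that("Levene is scale-equivariant and degenerate-safe", {
  g <- list(c(1, 4, 2, 5), c(10, 2, 8, 3))
  f1 <- levene_test(g)$statistic
  f2 <- levene_test(lapply(g, function(v) 7 * v))$statistic
  expect_equal(f1, f2)
  same <- levene_test(list(c(2, 2, 2), c(5, 5, 5)))
  expect_equal(same$statistic, 0)
  expect_equal(same$p, 1)
})

test_that("1.5-IQR outlier removal drops only fence violations, once", {
  expect_equal(remove_outliers(c(1, 2, 3, 4, 100)), c(1, 2, 3, 4))
  expect_equal(remove_outliers(c(1, 2, 3, 4, 5)), c(1, 2, 3, 4, 5))
  expect_equal(remove_outliers(rep(2, 6)), rep(2, 6))
  expect_warning(out <- remove_outliers(c(1, 2, 50)), "fewer than 4")
  expect_equal(out, c(1, 2, 50))
  set.seed(41)
  for (i in 1:25) {
    v <- rnorm(2 * sample(2:20, 1) + 1) + sample(c(0, 10), 1)  # odd n
    kept <- remove_outliers(v)
    expect_true(all(kept %in% v))
    expect_equal(kept, v[v %in% kept])          # order preserved
    expect_true(stats::median(v) %in% kept)     # median never removed
  }
})

test_that("compare_to_normal detects a shifted group and reports omnibus", {
  set.seed(51)
  base <- function(type, mu) tibble::tibble(
    subject = "S1", stride_type = type, measure = "leg_gap",
    value = rnorm(40, mu, 0.05))
  meas <- rbind(base("Normal", 1.5), base("Fast", 1.35), base("Slow", 1.5),
                base("RightAntalgic", 1.5), base("LeftAntalgic", 1.5))
  res <- compare_to_normal(meas, "S1", "leg_gap", "kruskal_wallis")
  expect_equal(res$stride_type,
               c("Fast", "Slow", "RightAntalgic", "LeftAntalgic", "All"))
  expect_true(res$significant[res$stride_type == "Fast"])
  expect_true(res$significant[res$stride_type == "All"])
  expect_equal(res$df[res$stride_type == "All"], 4)
  # missing stride type yields an explicit NA row, not an error
  partial <- meas[meas$stride_type != "Slow", ]
  res2 <- compare_to_normal(partial, "S1", "leg_gap", "kruskal_wallis")
  expect_true(is.na(res2$p[res2$stride_type == "Slow"]))
  expect_true(is.na(res2$p[res2$stride_type == "All"]))
})

test_that("outlier removal policy changes the groups actually tested", {
  set.seed(52)
  v <- c(rnorm(30, 1.5, 0.02), 1.1)  # one gross outlier in Normal
  meas <- tibble::tibble(
    subject = "S1",
    stride_type = rep(c("Normal", "Fast"), c(31, 30)),
    measure = "leg_gap",
    value = c(v, rnorm(30, 1.5, 0.1)))
  keep <- compare_to_normal(meas, "S1", "leg_gap", "levene",
                            outlier_policy = "keep")
  drop <- compare_to_normal(meas, "S1", "leg_gap", "levene",
                            outlier_policy = "remove")
  expect_false(isTRUE(all.equal(
    keep$statistic[keep$stride_type == "Fast"],
    drop$statistic[drop$stride_type == "Fast"])))
})

test_that("detection tabulation counts significant cells and unions", {
  p <- c(rep(0.01, 5), rep(0.5, 11))
  tab <- tabulate_detection(p, criterion = "gap_median")
  expect_equal(tab$n_significant, 5)
  expect_equal(tab$accuracy_pct, 31)
  expect_equal(tabulate_detection(rep(1, 16),
                                  criterion = "cadence_median")$accuracy_pct,
               0)
  p2 <- c(rep(0.5, 5), rep(0.01, 3), rep(0.5, 8))
  u <- tabulate_detection(p, criterion = "union", p2 = p2)
  expect_equal(u$n_significant, 8)
  # permutation invariance over cell ordering
  set.seed(61)
  ord <- sample(16)
  u2 <- tabulate_detection(p[ord], criterion = "union", p2 = p2[ord])
  expect_equal(u2$n_significant, u$n_significant)
  expect_error(tabulate_detection(p, criterion = "union"), "p2")
})
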