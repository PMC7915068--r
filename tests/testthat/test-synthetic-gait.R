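test_that("skew-normal sampler matches requested moments", {
  set.seed(71)
  for (g1 in c(-0.9, -0.5, 0, 0.7)) {
    x <- rskewnorm(2e5, mean = 1.5, sd = 0.05, skew = g1)
    expect_equal(mean(x), 1.5, tolerance = 5e-4)
    expect_equal(sd(x), 0.05, tolerance = 0.01)
    expect_equal(e1071::skewness(x, type = 1), g1, tolerance = 0.05)
  }
  expect_error(rskewnorm(10, skew = 1.2), "skew-normal")
  expect_error(rskewnorm(10, skew = -0.999), "skew-normal")
})

test_that("identical seeds reproduce identical traces", {
  p <- stride_type_params("Normal", 120, 2, 1.5, 0.05, -0.5, 20)
  s1 <- simulate_trace(p, simulation_config(seed = 5))
  s2 <- simulate_trace(p, simulation_config(seed = 5))
  expect_identical(s1$trace$code, s2$trace$code)
  expect_identical(s1$truth, s2$truth)
  s3 <- simulate_trace(p, simulation_config(seed = 6))
  expect_false(identical(s1$trace$code, s3$trace$code))
})

test_that("noise-free constant-cadence trace is recovered exactly", {
  p <- stride_type_params("Normal", 120, 0, 1.5, 0, 0, 25)
  cfg <- simulation_config(noise_sd_codes = 0, seed = 8)
  sim <- simulate_trace(p, cfg)
  ser <- process_trace(sim$trace)
  expect_equal(nrow(ser$peaks), 25)  # every injected event recovered
  expect_equal(ser$cadence$cadence, rep(120, 24))
  # leg gaps recovered to within one quantization step of the truth
  prec_cm <- estimate_precision(default_magnet, default_sensor, 0.9) / 10
  expect_true(all(abs(ser$peaks$leg_gap - 1.5) <= prec_cm + 1e-9))
})

test_that("detected peak times match ground truth stride for stride", {
  p <- stride_type_params("Fast", 134, 4, 1.55, 0.03, -0.4, 30)
  # noise-free: every event timed to within one sample period (off-grid
  # events quantize their plateau edges, so half a sample is only reachable
  # for events landing on the grid)
  cfg0 <- simulation_config(seed = 9, noise_sd_codes = 0)
  sim0 <- simulate_trace(p, cfg0)
  ser0 <- process_trace(sim0$trace)
  expect_equal(nrow(ser0$peaks), nrow(sim0$truth))
  expect_true(all(abs(ser0$peaks$t - sim0$truth$t) <= 1 / cfg0$sampling_hz +
                    1e-9))
  # on-grid events with no cadence jitter are timed exactly
  pg <- stride_type_params("Normal", 120, 0, 1.5, 0, 0, 10)
  simg <- simulate_trace(pg, simulation_config(seed = 1, noise_sd_codes = 0))
  serg <- process_trace(simg$trace)
  expect_equal(serg$peaks$t, simg$truth$t)
  # default noise can move the argmax within the quantization plateau of a
  # pulse top, but never by more than a few samples, and stays 1:1
  cfg <- simulation_config(seed = 9)
  sim <- simulate_trace(p, cfg)
  ser <- process_trace(sim$trace)
  expect_equal(nrow(ser$peaks), nrow(sim$truth))
  expect_true(all(abs(ser$peaks$t - sim$truth$t) <= 3 / cfg$sampling_hz))
})

test_that("generator parameters are recovered through the full pipeline", {
  p <- stride_type_params("Normal", 118, 3, 1.52, 0.04, -0.6, 200)
  # zero-noise tolerances: 0.5 steps/min on cadence, 0.02 cm on leg gap
  sim0 <- simulate_trace(p, simulation_config(noise_sd_codes = 0, seed = 10))
  ser0 <- process_trace(sim0$trace)
  expect_equal(mean(ser0$cadence$cadence), 118, tolerance = 0.5 / 118)
  expect_equal(mean(ser0$peaks$leg_gap, na.rm = TRUE), 1.52,
               tolerance = 0.02 / 1.52)
  # default-noise tolerances: 1.5 steps/min, 0.05 cm
  simn <- simulate_trace(p, simulation_config(seed = 10))
  sern <- process_trace(simn$trace)
  expect_equal(mean(sern$cadence$cadence), 118, tolerance = 1.5 / 118)
  expect_equal(mean(sern$peaks$leg_gap, na.rm = TRUE), 1.52,
               tolerance = 0.05 / 1.52)
})

test_that("larger leg-gap spread raises the expected Levene F", {
  f_for <- function(sd_hi, seed) {
    lo <- simulate_trace(stride_type_params("Normal", 120, 2, 1.5, 0.02,
                                            0, 40),
                         simulation_config(seed = seed))
    hi <- simulate_trace(stride_type_params("Fast", 120, 2, 1.5, sd_hi,
                                            0, 40),
                         simulation_config(seed = seed + 1))
    g1 <- process_trace(lo$trace)$peaks
    g2 <- process_trace(hi$trace)$peaks
    levene_test(list(g1$leg_gap[g1$in_range],
                     g2$leg_gap[g2$in_range]))$statistic
  }
  seeds <- 1:6
  f_mid <- mean(vapply(seeds, function(s) f_for(0.05, 100 + s), 1))
  f_big <- mean(vapply(seeds, function(s) f_for(0.09, 200 + s), 1))
  expect_gt(f_mid, 1)
  expect_gt(f_big, f_mid)
})

test_that("default cohort grid mirrors the published descriptives", {
  params <- default_cohort_params()
  expect_equal(nrow(params), 20)
  expect_setequal(unique(params$stride_type), stride_types)
  expect_true(all(params$n_strides >= 32 & params$n_strides <= 53))
  expect_true(all(abs(params$leg_gap_skew) <= 0.95))
  expect_equal(params$cadence_mean[params$subject == "S2" &
                                     params$stride_type == "Fast"], 134.17)
  expect_equal(params$leg_gap_mean[params$subject == "S1" &
                                     params$stride_type == "Normal"], 1.53)
})

test_that("a cohort with a strong cadence contrast is flagged by the tests", {
  params <- default_cohort_params()
  two <- params[params$subject == "S2", ]
  cohort <- make_cohort(two, seed = 12)
  res <- compare_to_normal(cohort$measurements, "S2", "cadence",
                           "kruskal_wallis")
  expect_true(res$significant[res$stride_type == "Fast"])
  expect_true(res$significant[res$stride_type == "Slow"])
})

test_that("cohort spec CSV round-trips", {
  params <- default_cohort_params()
  path <- tempfile(fileext = ".csv")
  write_cohort_spec(params, path)
  back <- read_cohort_spec(path)
  expect_equal(as.data.frame(back), as.data.frame(params))
  bad <- tempfile(fileext = ".csv")
  writeLines(c("subject,stride_type,cadence_mean",
               "S1,Sideways,100"), bad)
  expect_error(read_cohort_spec(bad), "unknown stride type")
})
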