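#' Skew-normal sampler matched to mean, SD and skewness
#'
#' Draws from a skew-normal distribution whose first three moments match the
#' requested mean, standard deviation and moment skewness `g1`. The
#' skew-normal family is used because nearly all observed leg-gap groups are
#' negatively skewed, so the generator must produce controllable `g1 < 0`.
#' Its reachable skewness is bounded (|g1| < ~0.9953); targets beyond that
#' are a parameter error.
#'
#' @param n Number of draws.
#' @param mean,sd Target mean and standard deviation.
#' @param skew Target moment skewness `g1`.
#' @return Numeric vector of length `n`.
#' @export
rskewnorm <- function(n, mean = 0, sd = 1, skew = 0) {
  stopifnot(n >= 0, sd > 0, is.finite(skew))
  g1_max <- 0.5 * (4 - pi) * (2 / pi)^1.5 / (1 - 2 / pi)^1.5  # ~0.9953
  if (abs(skew) >= g1_max)
    stop(sprintf("rskewnorm: |skew| must be < %.4f for a skew-normal",
                 g1_max), call. = FALSE)
  if (skew == 0) return(stats::rnorm(n, mean, sd))
  # Solve |g1(delta)| = |skew| for delta in (0, 1).
  g1_of <- function(delta) {
    m <- delta * sqrt(2 / pi)
    0.5 * (4 - pi) * m^3 / (1 - m^2)^1.5
  }
  delta <- stats::uniroot(function(d) g1_of(d) - abs(skew),
                          lower = 1e-9, upper = 1 - 1e-9, tol = 1e-12)$root
  delta <- sign(skew) * delta
  omega <- sd / sqrt(1 - 2 * delta^2 / pi)
  xi <- mean - omega * delta * sqrt(2 / pi)
  u1 <- stats::rnorm(n)
  u2 <- stats::rnorm(n)
  xi + omega * (delta * abs(u1) + sqrt(1 - delta^2) * u2)
}

#' Generative parameters for one subject x stride-type group
#'
#' @param stride_type One of [stride_types].
#' @param cadence_mean,cadence_sd Cadence distribution in steps/min
#'   (`cadence_mean` in (40, 150]: slower than 40 is not walking, faster
#'   than 150 exceeds the detectable ceiling at the default peak
#'   separation).
#' @param leg_gap_mean,leg_gap_sd Leg-gap distribution in cm.
#' @param leg_gap_skew Target moment skewness of the leg-gap distribution.
#' @param n_strides Number of strides to generate (>= 2).
#' @return A list of class `stride_type_params`.
#' @export
stride_type_params <- function(stride_type, cadence_mean, cadence_sd,
                               leg_gap_mean, leg_gap_sd,
                               leg_gap_skew = 0, n_strides = 40) {
  stopifnot(stride_type %in% stride_types,
            cadence_mean > 40, cadence_mean <= 150, cadence_sd >= 0,
            leg_gap_mean > 0, leg_gap_sd >= 0, n_strides >= 2)
  structure(list(stride_type = stride_type, cadence_mean = cadence_mean,
                 cadence_sd = cadence_sd, leg_gap_mean = leg_gap_mean,
                 leg_gap_sd = leg_gap_sd, leg_gap_skew = leg_gap_skew,
                 n_strides = as.integer(n_strides)),
            class = "stride_type_params")
}

#' Simulation settings for synthetic traces
#'
#' @param sampling_hz Sampling rate of the simulated logger; 250 Hz gives
#'   the 4 ms timing resolution of the prototype.
#' @param pulse_width_s Duration of the mid-stance approach/retreat dip in
#'   the inter-leg distance (must satisfy `sampling_hz > 2 / pulse_width_s`
#'   and be shorter than the shortest stride interval).
#' @param swing_distance_cm Inter-leg sensor-magnet distance away from
#'   mid-stance; chosen beyond the sensor range so the trace rests at
#'   baseline between strides.
#' @param noise_sd_codes Gaussian noise SD added in ADC code units.
#' @param seed Integer seed making the trace reproducible.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(sampling_hz = 250, pulse_width_s = 0.3,
                              swing_distance_cm = 6, noise_sd_codes = 2,
                              seed = NULL) {
  stopifnot(sampling_hz > 2 / pulse_width_s, pulse_width_s > 0,
            swing_distance_cm > 0, noise_sd_codes >= 0)
  structure(list(sampling_hz = sampling_hz, pulse_width_s = pulse_width_s,
                 swing_distance_cm = swing_distance_cm,
                 noise_sd_codes = noise_sd_codes, seed = seed),
            class = "simulation_config")
}

#' Simulate a sensor trace for one stride-type group
#'
#' Mid-stance times accumulate from per-stride intervals `120 / cadence_n`
#' with `cadence_n ~ Normal(cadence_mean, cadence_sd)`. Each stride's leg
#' gap is drawn from the moment-matched skew-normal; the inter-leg distance
#' trajectory rests at `swing_distance_cm` and makes a raised-cosine dip to
#' each stride's leg-gap-implied distance around its mid-stance time (the
#' analysis only uses the peak value and time, so any smooth unimodal pulse
#' works). Codes are the quantized Hall transfer of the field at that
#' distance, plus rounded Gaussian noise, clipped to the ADC range.
#'
#' @param params A [stride_type_params()].
#' @param config A [simulation_config()].
#' @param magnet,sensor,geom Physical model objects.
#' @return A list with `trace` (a [sensor_trace()]) and `truth`, a
#'   [tibble::tibble] of ground-truth per-stride `t` (mid-stance time, s),
#'   `leg_gap`, `x` and `cadence` (steps/min; `NA` for the first stride).
#' @export
simulate_trace <- function(params, config = simulation_config(),
                           magnet = ring_magnet(), sensor = hall_sensor(),
                           geom = mount_geometry()) {
  stopifnot(inherits(params, "stride_type_params"),
            inherits(config, "simulation_config"))
  offset <- magnet$T + geom$W_sensor_board
  if (params$leg_gap_mean <= offset)
    stop("simulate_trace: leg_gap_mean must exceed magnet thickness plus ",
         "sensor/board width", call. = FALSE)
  if (!is.null(config$seed)) set.seed(config$seed)

  n <- params$n_strides
  cadence <- stats::rnorm(n, params$cadence_mean, params$cadence_sd)
  cadence <- pmax(cadence, 30)  # guard absurd draws at extreme sd
  intervals <- 120 / cadence    # one mid-stance event per stride, seconds
  t_peak <- 1 + cumsum(c(0, intervals[-1]))
  leg_gap <- if (params$leg_gap_sd == 0) rep(params$leg_gap_mean, n) else
    rskewnorm(n, params$leg_gap_mean, params$leg_gap_sd, params$leg_gap_skew)
  x_peak <- pmax(leg_gap - offset, 0.05)

  dt <- 1 / config$sampling_hz
  t <- seq(0, max(t_peak) + 1, by = dt)
  xtraj <- rep(config$swing_distance_cm, length(t))
  half <- config$pulse_width_s / 2
  for (k in seq_len(n)) {
    sel <- which(abs(t - t_peak[k]) < half)
    dip <- 0.5 * (1 + cos(pi * (t[sel] - t_peak[k]) / half))
    xtraj[sel] <- pmin(xtraj[sel], config$swing_distance_cm -
                         (config$swing_distance_cm - x_peak[k]) * dip)
  }
  v <- sensor_voltage(axial_field(magnet, xtraj), sensor)
  code <- adc_code(v, sensor)
  if (config$noise_sd_codes > 0) {
    code <- code + as.integer(round(stats::rnorm(length(code), 0,
                                                 config$noise_sd_codes)))
    code <- pmin(pmax(code, 0L), sensor$full_scale)
  }
  trace <- sensor_trace(round(t * 1000), code,
                        meta = list(stride_type = params$stride_type,
                                    sampling_hz = config$sampling_hz),
                        adc_bits = sensor$adc_bits)
  truth <- tibble::tibble(t = t_peak, leg_gap = leg_gap, x = x_peak,
                          cadence = c(NA_real_, cadence[-1]))
  list(trace = trace, truth = truth)
}

#' Default cohort parameter grid
#'
#' Generative parameters for the emulated four-subject, five-stride-type
#' cohort: per-cell leg-gap mean/SD/skewness and stride counts, and cadence
#' mean/SD, set to the published descriptive statistics of the study
#' cohort. Skewness targets beyond the skew-normal reachable range are
#' clamped to +/-0.95.
#'
#' @return A [tibble::tibble] with one row per subject x stride type:
#'   `subject`, `stride_type`, `cadence_mean`, `cadence_sd`,
#'   `leg_gap_mean`, `leg_gap_sd`, `leg_gap_skew`, `n_strides`.
#' @export
default_cohort_params <- function() {
  d <- published_descriptives()
  gap <- d[d$measure == "leg_gap", ]
  cad <- d[d$measure == "cadence", ]
  key <- paste(gap$subject, gap$stride_type)
  ckey <- paste(cad$subject, cad$stride_type)
  m <- match(key, ckey)
  tibble::tibble(
    subject = gap$subject,
    stride_type = gap$stride_type,
    cadence_mean = cad$mean[m],
    cadence_sd = cad$sd[m],
    leg_gap_mean = gap$mean,
    leg_gap_sd = gap$sd,
    leg_gap_skew = pmin(pmax(gap$skewness, -0.95), 0.95),
    n_strides = gap$n)
}

#' Simulate and process a full cohort
#'
#' Runs [simulate_trace()] and [process_trace()] for every row of the
#' parameter grid and collects per-stride leg-gap and cadence measurements
#' in the long format the statistical battery consumes. Per-cell seeds are
#' derived deterministically from `seed`.
#'
#' @param params Parameter grid as from [default_cohort_params()].
#' @param config A [simulation_config()]; its `seed` element is ignored in
#'   favour of `seed`.
#' @param magnet,sensor,geom Physical model objects.
#' @param seed Master integer seed.
#' @param min_separation,prominence_fraction Peak-detection settings.
#' @return A list with `measurements` (long tibble: `subject`,
#'   `stride_type`, `measure`, `value`) and `cells` (per-cell bookkeeping:
#'   strides generated, peaks detected, peaks out of range).
#' @export
make_cohort <- function(params = default_cohort_params(),
                        config = simulation_config(),
                        magnet = ring_magnet(), sensor = hall_sensor(),
                        geom = mount_geometry(), seed = 1L,
                        min_separation = 0.8, prominence_fraction = 0.25) {
  stopifnot(is.data.frame(params), nrow(params) >= 1)
  need <- c("subject", "stride_type", "cadence_mean", "cadence_sd",
            "leg_gap_mean", "leg_gap_sd", "leg_gap_skew", "n_strides")
  if (!all(need %in% names(params)))
    stop("make_cohort: params is missing columns: ",
         paste(setdiff(need, names(params)), collapse = ", "), call. = FALSE)
  meas <- vector("list", nrow(params))
  cells <- vector("list", nrow(params))
  for (i in seq_len(nrow(params))) {
    p <- params[i, ]
    stp <- stride_type_params(p$stride_type, p$cadence_mean, p$cadence_sd,
                              p$leg_gap_mean, p$leg_gap_sd, p$leg_gap_skew,
                              p$n_strides)
    cfg <- config
    cfg$seed <- (as.integer(seed) * 97L + i) %% 2147483647L
    sim <- simulate_trace(stp, cfg, magnet, sensor, geom)
    ser <- process_trace(sim$trace, magnet, sensor, geom,
                         min_separation = min_separation,
                         prominence_fraction = prominence_fraction)
    gaps <- ser$peaks$leg_gap[ser$peaks$in_range]
    cad <- ser$cadence$cadence
    meas[[i]] <- tibble::tibble(
      subject = p$subject, stride_type = p$stride_type,
      measure = rep(c("leg_gap", "cadence"), c(length(gaps), length(cad))),
      value = c(gaps, cad))
    cells[[i]] <- tibble::tibble(
      subject = p$subject, stride_type = p$stride_type,
      n_strides = p$n_strides, n_peaks = ser$counts[["n_peaks"]],
      n_out_of_range = ser$counts[["n_out_of_range"]])
  }
  list(measurements = do.call(rbind, meas), cells = do.call(rbind, cells))
}

#' Read / write a cohort specification CSV
#'
#' Columns `subject`, `stride_type`, `cadence_mean`, `cadence_sd`,
#' `leg_gap_mean`, `leg_gap_sd`, `leg_gap_skew`, `n_strides`.
#'
#' @param path File path.
#' @return `read_cohort_spec` returns a parameter tibble;
#'   `write_cohort_spec` returns `path` invisibly.
#' @export
read_cohort_spec <- function(path) {
  if (!file.exists(path))
    stop(sprintf("cohort spec not found: %s", path), call. = FALSE)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  bad <- setdiff(unique(d$stride_type), stride_types)
  if (length(bad))
    stop(sprintf("%s: unknown stride type(s): %s", path,
                 paste(bad, collapse = ", ")), call. = FALSE)
  tibble::as_tibble(d)
}

#' @rdname read_cohort_spec
#' @param params Parameter tibble.
#' @export
write_cohort_spec <- function(params, path) {
  utils::write.csv(params, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
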