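#' Construct a sensor trace
#'
#' A timestamped sequence of raw ADC codes as logged from the wearable.
#'
#' @param time_ms Strictly increasing timestamps in integer milliseconds.
#' @param code Integer ADC codes, one per timestamp.
#' @param meta Optional named list of provenance (subject label, stride-type
#'   label, sampling notes).
#' @param adc_bits ADC resolution used to validate the codes.
#' @return An object of class `sensor_trace`.
#' @export
sensor_trace <- function(time_ms, code, meta = list(), adc_bits = 10) {
  stopifnot(is.numeric(time_ms), is.numeric(code),
            length(time_ms) == length(code))
  if (length(time_ms) == 0)
    stop("sensor_trace: empty trace", call. = FALSE)
  if (any(diff(time_ms) <= 0))
    stop("sensor_trace: timestamps must be strictly increasing", call. = FALSE)
  if (any(code < 0 | code > 2^adc_bits - 1 | code != round(code)))
    stop("sensor_trace: codes outside ADC range", call. = FALSE)
  structure(list(time_ms = as.integer(round(time_ms)),
                 code = as.integer(code), meta = meta),
            class = "sensor_trace")
}

#' @export
print.sensor_trace <- function(x, ...) {
  dur <- (x$time_ms[length(x$time_ms)] - x$time_ms[1]) / 1000
  cat(sprintf("<sensor_trace> %d samples over %.1f s, codes %d..%d\n",
              length(x$code), dur, min(x$code), max(x$code)))
  invisible(x)
}

#' Read / write the trace CSV dialect
#'
#' Two integer columns with header `time_ms,code`. The writer emits the
#' identical dialect (no quoting, no float formatting), so a write/read
#' round trip is bit-exact.
#'
#' @param path File path.
#' @param meta Passed to [sensor_trace()] on read.
#' @return `read_trace_csv` returns a `sensor_trace`; `write_trace_csv`
#'   returns `path` invisibly.
#' @export
read_trace_csv <- function(path, meta = list()) {
  if (!file.exists(path))
    stop(sprintf("trace file not found: %s", path), call. = FALSE)
  d <- utils::read.csv(path, colClasses = "integer")
  if (!identical(names(d), c("time_ms", "code")))
    stop(sprintf("%s:1: expected header 'time_ms,code'", path), call. = FALSE)
  sensor_trace(d$time_ms, d$code, meta = meta)
}

#' @rdname read_trace_csv
#' @param trace A `sensor_trace`.
#' @export
write_trace_csv <- function(trace, path) {
  stopifnot(inherits(trace, "sensor_trace"))
  utils::write.csv(data.frame(time_ms = trace$time_ms, code = trace$code),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Plateau-aware local maxima: returns the center index of every run of equal
# values that strictly exceeds both neighbouring runs. Boundary runs are
# never maxima.
local_maxima <- function(y) {
  r <- rle(y)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  k <- length(r$values)
  if (k < 3) return(integer(0))
  mid <- 2:(k - 1)
  is_max <- r$values[mid] > r$values[mid - 1] & r$values[mid] > r$values[mid + 1]
  runs <- mid[is_max]
  as.integer(floor((starts[runs] + ends[runs]) / 2))
}

#' Detect mid-stance peaks in a sensor trace
#'
#' Mid-stance (the swinging leg passing the stance leg) produces the maximum
#' sensor output of each stride. Candidate local maxima (plateau-aware, so a
#' quantization-flattened peak is timed at its center) are thinned so that no
#' two retained peaks are closer than `min_separation` seconds, keeping the
#' larger code when two conflict (earlier time on ties). Retained maxima are
#' then filtered by prominence above the trace baseline: peaks below
#' `prominence_fraction` times the median candidate prominence are discarded
#' as spurious low-signal maxima. The default 0.8 s separation corresponds
#' to a maximum detectable cadence of 150 steps/min.
#'
#' @param trace A [sensor_trace()].
#' @param min_separation Minimum time between peaks, in seconds.
#' @param prominence_fraction Fraction of the median candidate prominence
#'   below which a peak is discarded (in `[0, 1]`).
#' @param baseline_code Baseline used for prominence; defaults to the median
#'   code of the trace (between strides the magnet is out of range, so most
#'   samples sit at the baseline).
#' @return A [tibble::tibble] with columns `t` (peak time, seconds), `code`
#'   and `index` (sample index), ordered by time. Attribute `n_dropped`
#'   records how many candidates the prominence filter removed.
#' @export
detect_mid_stance_peaks <- function(trace, min_separation = 0.8,
                                    prominence_fraction = 0.25,
                                    baseline_code = NULL) {
  stopifnot(inherits(trace, "sensor_trace"), min_separation > 0,
            prominence_fraction >= 0, prominence_fraction <= 1)
  t <- trace$time_ms / 1000
  y <- trace$code
  idx <- local_maxima(y)
  empty <- tibble::tibble(t = numeric(0), code = integer(0),
                          index = integer(0))
  if (!length(idx)) return(structure(empty, n_dropped = 0L))

  # Greedy minimum-separation thinning: descending code, ties earlier time.
  ord <- idx[order(-y[idx], t[idx])]
  kept <- integer(0)
  for (i in ord) {
    if (!length(kept) || all(abs(t[i] - t[kept]) >= min_separation))
      kept <- c(kept, i)
  }
  kept <- sort(kept)

  if (is.null(baseline_code)) baseline_code <- stats::median(y)
  prom <- y[kept] - baseline_code
  ok <- prom > 0
  med_prom <- if (any(ok)) stats::median(prom[ok]) else 0
  keep <- ok & prom >= prominence_fraction * med_prom
  res <- tibble::tibble(t = t[kept[keep]], code = y[kept[keep]],
                        index = kept[keep])
  structure(res, n_dropped = sum(!keep))
}

#' Leg-gap width at each mid-stance peak
#'
#' Runs the decode -> field -> distance inversion chain on the peak codes
#' and converts the recovered sensor-magnet distances to leg-gap widths.
#' Peaks whose code cannot be resolved (at/below baseline or outside the
#' field model's monotone domain) are flagged `in_range = FALSE` with `NA`
#' leg gap, and should be excluded from downstream statistics.
#'
#' @param peaks Peak table from [detect_mid_stance_peaks()].
#' @param magnet A [ring_magnet()].
#' @param sensor A [hall_sensor()].
#' @param geom A [mount_geometry()].
#' @param x_max Inversion bracket far edge, in cm.
#' @return `peaks` with added columns `v`, `B`, `x`, `leg_gap`, `in_range`.
#' @export
compute_leg_gaps <- function(peaks, magnet, sensor, geom, x_max = 6) {
  stopifnot(is.data.frame(peaks), all(c("t", "code") %in% names(peaks)))
  if (!nrow(peaks)) {
    peaks$v <- peaks$B <- peaks$x <- peaks$leg_gap <- numeric(0)
    peaks$in_range <- logical(0)
    return(peaks)
  }
  v <- decode_adc(peaks$code, sensor)
  inv <- invert_to_distance(v, magnet, sensor, x_max = x_max)
  peaks$v <- inv$v
  peaks$B <- inv$B
  peaks$x <- inv$x
  peaks$leg_gap <- ifelse(inv$in_range,
                          leg_gap_width(ifelse(is.na(inv$x), 0, inv$x),
                                        magnet, geom),
                          NA_real_)
  peaks$in_range <- inv$in_range
  peaks
}

#' Strides per minute and cadence from peak times
#'
#' One mid-stance peak is seen per stride (only the left-leg swing brings
#' the magnet past the sensor), so strides per minute for stride n is
#' `60 / (t_n - t_{n-1})` and cadence (steps per minute) is twice that.
#'
#' @param peaks Peak table from [detect_mid_stance_peaks()].
#' @return A [tibble::tibble] with one row per adjacent peak pair
#'   (attributed to the later stride): `t`, `strides_per_min`, `cadence`.
#'   Empty (zero rows) when fewer than two peaks are available.
#' @export
compute_cadence <- function(peaks) {
  stopifnot(is.data.frame(peaks), "t" %in% names(peaks))
  if (nrow(peaks) < 2)
    return(tibble::tibble(t = numeric(0), strides_per_min = numeric(0),
                          cadence = numeric(0)))
  dt <- diff(peaks$t)
  spm <- 60 / dt
  tibble::tibble(t = peaks$t[-1], strides_per_min = spm, cadence = 2 * spm)
}

#' Full per-trace stride pipeline
#'
#' Peak detection, leg-gap inversion and cadence computation in one call.
#'
#' @inheritParams detect_mid_stance_peaks
#' @inheritParams compute_leg_gaps
#' @return A list of class `stride_series` with elements `peaks` (per-peak
#'   table including leg gaps), `cadence` (per-stride-pair table) and
#'   `counts` (peaks found, dropped by prominence, out of range).
#' @export
process_trace <- function(trace, magnet = ring_magnet(),
                          sensor = hall_sensor(), geom = mount_geometry(),
                          min_separation = 0.8, prominence_fraction = 0.25,
                          x_max = 6) {
  peaks <- detect_mid_stance_peaks(trace, min_separation = min_separation,
                                   prominence_fraction = prominence_fraction,
                                   baseline_code = NULL)
  n_dropped <- attr(peaks, "n_dropped")
  peaks <- compute_leg_gaps(peaks, magnet, sensor, geom, x_max = x_max)
  structure(list(peaks = peaks,
                 cadence = compute_cadence(peaks),
                 counts = c(n_peaks = nrow(peaks),
                            n_dropped_prominence = n_dropped,
                            n_out_of_range = sum(!peaks$in_range))),
            class = "stride_series")
}

#' @export
print.stride_series <- function(x, ...) {
  cat(sprintf(
    "<stride_series> %d peaks (%d dropped by prominence, %d out of range)\n",
    x$counts[["n_peaks"]], x$counts[["n_dropped_prominence"]],
    x$counts[["n_out_of_range"]]))
  invisible(x)
}

#' Write a per-stride table for a processed trace
#'
#' One row per detected peak: time, code, leg gap (cm), in-range flag, and
#' the cadence attributed to the stride ending at that peak (`NA` for the
#' first peak).
#'
#' @param series A `stride_series` from [process_trace()].
#' @param path Output CSV path.
#' @export
write_stride_csv <- function(series, path) {
  stopifnot(inherits(series, "stride_series"))
  p <- series$peaks
  cad <- if (nrow(p)) c(NA_real_, series$cadence$cadence) else numeric(0)
  d <- data.frame(t = p$t, code = p$code,
                  leg_gap_cm = round(p$leg_gap, 12),
                  in_range = p$in_range,
                  cadence_steps_min = round(cad, 12))
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
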