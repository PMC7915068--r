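#' Ring magnet description
#'
#' Geometry and remanence of the axially magnetized ring magnet worn on the
#' leg opposite the sensor. Defaults describe a 1-inch OD, 5/16-inch ID,
#' 1/8-inch thick N52 neodymium ring (remanence 14,800 G).
#'
#' @param Br Remanent (surface) magnetic field in Gauss. Must be positive.
#' @param Ro Outer radius in cm.
#' @param Ri Inner radius in cm (0 for a solid disk magnet).
#' @param T Axial thickness in cm.
#'
#' @return An object of class `ring_magnet`.
#' @export
#' @examples
#' m <- ring_magnet()
#' axial_field(m, 1)  # field on axis 1 cm from the face, in Gauss
ring_magnet <- function(Br = 14800, Ro = 1.27, Ri = 0.397, T = 0.3175) {
  stopifnot(is.numeric(Br), length(Br) == 1, Br > 0,
            is.numeric(Ro), length(Ro) == 1,
            is.numeric(Ri), length(Ri) == 1,
            is.numeric(T),  length(T) == 1, T > 0)
  if (!(Ro > Ri && Ri >= 0))
    stop("ring_magnet: need Ro > Ri >= 0", call. = FALSE)
  structure(list(Br = Br, Ro = Ro, Ri = Ri, T = T), class = "ring_magnet")
}

#' Hall-effect sensor description
#'
#' A continuous-time ratiometric linear Hall-effect sensor: output voltage is
#' `S * B + Vdd/2`, clipped to the supply rails, and digitized by an ADC.
#' The zero-field baseline sits at half the supply voltage.
#'
#' @param S Sensitivity in mV/G (datasheet range 1.3-1.6 mV/G for the A1302
#'   class of parts; default is the midpoint 1.45). Stored internally in V/G.
#' @param Vdd Supply voltage in volts.
#' @param adc_bits ADC resolution in bits.
#' @param baseline_code Integer ADC code corresponding to zero field
#'   (nominally `Vdd/2`, i.e. 511 or 512 for a 10-bit converter).
#'
#' @return An object of class `hall_sensor` with element `S` in V/G.
#' @export
hall_sensor <- function(S = 1.45, Vdd = 5, adc_bits = 10, baseline_code = 512) {
  stopifnot(is.numeric(S), length(S) == 1, S > 0,
            is.numeric(Vdd), length(Vdd) == 1, Vdd > 0,
            is.numeric(adc_bits), length(adc_bits) == 1, adc_bits >= 1)
  full_scale <- 2^adc_bits - 1
  if (baseline_code < 0 || baseline_code > full_scale)
    stop("hall_sensor: baseline_code outside ADC range", call. = FALSE)
  structure(list(S = S / 1000, Vdd = Vdd, adc_bits = as.integer(adc_bits),
                 baseline_code = as.integer(baseline_code),
                 full_scale = full_scale),
            class = "hall_sensor")
}

#' Sensor mounting geometry
#'
#' @param W_sensor_board Combined width of the sensor package and the circuit
#'   board it is mounted on, in cm. Added (together with the magnet
#'   thickness) to the sensor-magnet distance to obtain the leg-gap width.
#'
#' @return An object of class `mount_geometry`.
#' @export
mount_geometry <- function(W_sensor_board = 0.28) {
  stopifnot(is.numeric(W_sensor_board), length(W_sensor_board) == 1,
            W_sensor_board >= 0)
  structure(list(W_sensor_board = W_sensor_board), class = "mount_geometry")
}

#' @export
print.ring_magnet <- function(x, ...) {
  cat(sprintf("<ring_magnet> Br = %g G, Ro = %g cm, Ri = %g cm, T = %g cm\n",
              x$Br, x$Ro, x$Ri, x$T))
  invisible(x)
}

#' @export
print.hall_sensor <- function(x, ...) {
  cat(sprintf(
    "<hall_sensor> S = %g mV/G, Vdd = %g V, %d-bit ADC, baseline code %d\n",
    x$S * 1000, x$Vdd, x$adc_bits, x$baseline_code))
  invisible(x)
}

# On-axis field of a uniformly magnetized disk, distance x from one face.
disk_field <- function(x, R, T, Br) {
  (Br / 2) * ((x + T) / sqrt(R^2 + (x + T)^2) - x / sqrt(R^2 + x^2))
}

#' On-axis magnetic field of a ring magnet
#'
#' Axial field at distance `x` from the magnet face, by superposition of an
#' outer disk and an oppositely magnetized inner disk. For a ring with a
#' nonzero bore the field reverses sign very close to the face and peaks a
#' short distance out; beyond that peak it decays monotonically (approaching
#' the dipole x^-3 law far away), which is the regime the sensor operates in.
#'
#' @param magnet A [ring_magnet()].
#' @param x Distance(s) from the magnet face along its axis, in cm
#'   (non-negative).
#' @return Field in Gauss, same length as `x`.
#' @export
axial_field <- function(magnet, x) {
  stopifnot(inherits(magnet, "ring_magnet"), is.numeric(x))
  if (any(x < 0)) stop("axial_field: x must be non-negative", call. = FALSE)
  disk_field(x, magnet$Ro, magnet$T, magnet$Br) -
    disk_field(x, magnet$Ri, magnet$T, magnet$Br)
}

#' Location of the on-axis field maximum
#'
#' For a solid disk (`Ri = 0`) the field is largest at the face and the
#' resolvable domain starts at 0. For a ring, the bore reverses the field
#' near the face; distances closer than the field peak cannot be recovered
#' uniquely from a field reading, so the peak marks the near edge of the
#' sensor's resolvable domain.
#'
#' @param magnet A [ring_magnet()].
#' @return Distance of the field maximum from the face, in cm.
#' @export
field_peak_x <- function(magnet) {
  stopifnot(inherits(magnet, "ring_magnet"))
  if (magnet$Ri == 0) return(0)
  stats::optimize(function(x) axial_field(magnet, x),
                  interval = c(0, 10 * magnet$Ro), maximum = TRUE)$maximum
}

#' Decode an ADC code to a voltage
#'
#' Inverse of the converter: `Vdd / (2^bits - 1) * code` (so full scale maps
#' to `Vdd` exactly and code 0 to 0 V).
#'
#' @param code Integer ADC code(s), each in `[0, 2^bits - 1]`.
#' @param sensor A [hall_sensor()].
#' @return Voltage(s) in volts.
#' @export
decode_adc <- function(code, sensor) {
  stopifnot(inherits(sensor, "hall_sensor"), is.numeric(code))
  if (any(code < 0 | code > sensor$full_scale) || any(code != round(code)))
    stop("decode_adc: code outside ADC range", call. = FALSE)
  sensor$Vdd / sensor$full_scale * code
}

#' Quantize a voltage to an ADC code
#'
#' Round-to-nearest quantization, clipped to the converter range. This is
#' the forward converter used by the simulator.
#'
#' @inheritParams decode_adc
#' @param v Voltage(s) in volts.
#' @return Integer code(s).
#' @export
adc_code <- function(v, sensor) {
  stopifnot(inherits(sensor, "hall_sensor"))
  as.integer(pmin(pmax(round(v / sensor$Vdd * sensor$full_scale), 0),
                  sensor$full_scale))
}

#' Hall transfer function: field to output voltage
#'
#' @param B Field(s) in Gauss.
#' @param sensor A [hall_sensor()].
#' @return Output voltage(s), `S*B + Vdd/2` clipped to `[0, Vdd]`.
#' @export
sensor_voltage <- function(B, sensor) {
  stopifnot(inherits(sensor, "hall_sensor"), is.numeric(B))
  pmin(pmax(sensor$S * B + sensor$Vdd / 2, 0), sensor$Vdd)
}

#' Invert a sensor voltage to a sensor-magnet distance
#'
#' Numerically inverts the forward chain field-model -> Hall transfer on the
#' monotone (beyond-field-peak) branch by root bisection, to a tolerance of
#' 1e-6 cm. Voltages at or below the zero-field baseline, or implying a
#' field stronger than the on-axis maximum or weaker than the field at
#' `x_max`, are flagged out of range rather than inverted.
#'
#' @param v Output voltage(s) in volts.
#' @param magnet A [ring_magnet()].
#' @param sensor A [hall_sensor()].
#' @param x_max Far edge of the inversion bracket, in cm.
#' @return A [tibble::tibble] with one row per voltage and columns `v`, `B`
#'   (implied field, Gauss), `x` (distance, cm; `NA` when out of range) and
#'   `in_range`.
#' @export
invert_to_distance <- function(v, magnet, sensor, x_max = 6) {
  stopifnot(inherits(magnet, "ring_magnet"), inherits(sensor, "hall_sensor"),
            is.numeric(v), x_max > 0)
  x_lo <- field_peak_x(magnet)
  if (x_lo >= x_max)
    stop("invert_to_distance: x_max lies inside the non-resolvable zone",
         call. = FALSE)
  B_hi <- axial_field(magnet, x_lo)
  B_lo <- axial_field(magnet, x_max)
  if (B_hi <= B_lo)
    stop("invert_to_distance: field model is not decreasing on the bracket",
         call. = FALSE)
  B_target <- (v - sensor$Vdd / 2) / sensor$S
  x <- rep(NA_real_, length(v))
  ok <- v > sensor$Vdd / 2 & B_target >= B_lo & B_target <= B_hi
  for (i in which(ok)) {
    x[i] <- stats::uniroot(function(z) axial_field(magnet, z) - B_target[i],
                           lower = x_lo, upper = x_max, tol = 1e-7)$root
  }
  tibble::tibble(v = v, B = B_target, x = x, in_range = ok)
}

#' Leg-gap width from sensor-magnet distance
#'
#' The leg gap (distance between the legs at the mounting height, the proxy
#' for stride width) is the sensor-face-to-magnet-face distance plus the
#' magnet thickness plus the sensor/board width.
#'
#' @param x Distance(s) from sensor face to magnet face, in cm
#'   (non-negative).
#' @param magnet A [ring_magnet()] (supplies the thickness).
#' @param geom A [mount_geometry()].
#' @return Leg-gap width(s) in cm.
#' @export
leg_gap_width <- function(x, magnet, geom) {
  stopifnot(inherits(magnet, "ring_magnet"), inherits(geom, "mount_geometry"),
            is.numeric(x))
  if (any(x < 0, na.rm = TRUE))
    stop("leg_gap_width: x must be non-negative", call. = FALSE)
  x + magnet$T + geom$W_sensor_board
}

#' Distance resolution of one ADC step
#'
#' The distance change equivalent to one least-significant ADC bit at
#' operating point `x`: `dV_LSB / (S * |dB/dx|)`, with the field slope taken
#' by central difference. This is the quantization-limited precision of the
#' leg-gap measurement.
#'
#' @param magnet A [ring_magnet()].
#' @param sensor A [hall_sensor()].
#' @param x Operating distance in cm (inside the resolvable domain).
#' @param h Central-difference step in cm.
#' @return Precision in mm per ADC state.
#' @export
estimate_precision <- function(magnet, sensor, x, h = 1e-4) {
  stopifnot(inherits(magnet, "ring_magnet"), inherits(sensor, "hall_sensor"),
            is.numeric(x), all(x > h))
  dBdx <- (axial_field(magnet, x + h) - axial_field(magnet, x - h)) / (2 * h)
  if (any(abs(dBdx) < 1e-9))
    stop("estimate_precision: field slope vanishes at x (out of range)",
         call. = FALSE)
  dV_lsb <- sensor$Vdd / sensor$full_scale
  10 * dV_lsb / (sensor$S * abs(dBdx))  # cm -> mm
}

#' Usable range of the sensor-magnet pair
#'
#' Scans outward from the near edge of the resolvable domain and reports the
#' smallest distance at which moving the magnet `increment` cm further
#' changes the quantized sensor output by fewer than `min_states` ADC
#' states, i.e. the point where the digital output stops resolving magnet
#' motion at that granularity.
#'
#' @param magnet A [ring_magnet()].
#' @param sensor A [hall_sensor()].
#' @param increment Displacement increment in cm.
#' @param min_states Minimum required code change over `increment`.
#' @param step Scan grid step in cm.
#' @param x_scan_max Upper end of the scan window in cm.
#' @return Range in cm (the scan upper bound, with a warning, if the
#'   criterion is never met).
#' @export
estimate_range <- function(magnet, sensor, increment = 0.16, min_states = 2,
                           step = 0.01, x_scan_max = 12) {
  stopifnot(inherits(magnet, "ring_magnet"), inherits(sensor, "hall_sensor"),
            increment > 0, min_states >= 1, step > 0)
  xs <- seq(field_peak_x(magnet) + step, x_scan_max, by = step)
  code_at <- function(x)
    adc_code(sensor_voltage(axial_field(magnet, x), sensor), sensor)
  drop <- code_at(xs) - code_at(xs + increment)
  hit <- which(drop < min_states)
  if (!length(hit)) {
    warning("estimate_range: criterion not met within scan window")
    return(x_scan_max)
  }
  xs[hit[1]]
}

#' Read a plain-text sensor configuration file
#'
#' INI-style key-value file with sections `[magnet]` (`Br`, `Ro`, `Ri`, `T`),
#' `[sensor]` (`S` in mV/G, `Vdd`, `adc_bits`, `baseline_code`) and `[mount]`
#' (`W_sensor_board`). Lines starting with `#` or `;` are comments. Missing
#' keys fall back to the package defaults.
#'
#' @param path Path to the configuration file.
#' @return A list with elements `magnet`, `sensor` and `geom`.
#' @export
read_gait_config <- function(path) {
  if (!file.exists(path))
    stop(sprintf("config file not found: %s", path), call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  section <- ""
  vals <- list(magnet = list(), sensor = list(), mount = list())
  for (i in seq_along(lines)) {
    ln <- trimws(sub("[#;].*$", "", lines[i]))
    if (ln == "") next
    if (grepl("^\\[.+\\]$", ln)) {
      section <- tolower(gsub("\\[|\\]", "", ln))
      if (!section %in% names(vals))
        stop(sprintf("%s:%d: unknown section [%s]", path, i, section),
             call. = FALSE)
      next
    }
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2 || section == "")
      stop(sprintf("%s:%d: malformed line '%s'", path, i, lines[i]),
           call. = FALSE)
    key <- trimws(kv[1])
    num <- suppressWarnings(as.numeric(trimws(kv[2])))
    if (is.na(num))
      stop(sprintf("%s:%d: value for '%s' is not numeric", path, i, key),
           call. = FALSE)
    vals[[section]][[key]] <- num
  }
  call_with <- function(f, args) do.call(f, args[names(args) %in%
                                                   names(formals(f))])
  list(magnet = call_with(ring_magnet, vals$magnet),
       sensor = call_with(hall_sensor, vals$sensor),
       geom = call_with(mount_geometry, vals$mount))
}
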