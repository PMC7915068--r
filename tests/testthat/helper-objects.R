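# Shared fixtures and independent oracles, built in code.

default_magnet <- ring_magnet()
default_sensor <- hall_sensor()
default_geom <- mount_geometry()

# Synthetic trace of triangular pulses on a flat baseline: peak_t in seconds,
# peak_code the apex codes, width the pulse base in seconds.
pulse_trace <- function(peak_t, peak_code, baseline = 512, width = 0.2,
                        fs = 250, duration = max(peak_t) + 1) {
  t <- seq(0, duration, by = 1 / fs)
  y <- rep(baseline, length(t))
  for (k in seq_along(peak_t)) {
    sel <- which(abs(t - peak_t[k]) <= width / 2)
    frac <- 1 - abs(t[sel] - peak_t[k]) / (width / 2)
    y[sel] <- pmax(y[sel], round(baseline + (peak_code[k] - baseline) * frac))
  }
  sensor_trace(round(t * 1000), y)
}

# Tie-corrected Kruskal-Wallis H, straight from the rank-sum definition.
kw_H_oracle <- function(groups) {
  x <- unlist(groups, use.names = FALSE)
  g <- rep(seq_along(groups), lengths(groups))
  r <- rank(x)
  n <- length(x)
  H <- 12 / (n * (n + 1)) *
    sum(tapply(r, g, sum)^2 / tabulate(g)) - 3 * (n + 1)
  ties <- table(x)
  H / (1 - sum(ties^3 - ties) / (n^3 - n))
}

# Brute-force one-way ANOVA F on absolute deviations from group means.
levene_F_oracle <- function(groups) {
  z <- lapply(groups, function(v) abs(v - mean(v)))
  zall <- unlist(z, use.names = FALSE)
  k <- length(z)
  N <- length(zall)
  ssb <- sum(lengths(z) * (vapply(z, mean, 1) - mean(zall))^2)
  ssw <- sum(unlist(lapply(z, function(v) (v - mean(v))^2)))
  (ssb / (k - 1)) / (ssw / (N - k))
}
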