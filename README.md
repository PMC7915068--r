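# hallgait

Analysis toolkit for a wearable gait monitor built from a single linear
Hall-effect sensor worn just above one knee and a compact axially
magnetized ring magnet on the opposite leg. Each time the swinging leg
passes the stance leg (mid-stance) the legs are closest and the sensor
output peaks; from the stream of 10-bit ADC codes the package recovers

* the **leg gap** — the inter-leg distance at the mounting height, a proxy
  for stride width — from each mid-stance peak, by inverting a ring-magnet
  field model, and
* **cadence** from the times of successive peaks,

then runs the nonparametric battery that decides whether abnormal
(fast/slow) or irregular (antalgic, i.e. limping) stride types differ from
a wearer's normal gait. It is aimed at researchers in wearable gait
analysis who want a tested, reproducible reference implementation of this
measurement principle, including a seeded synthetic-trace generator so the
whole chain runs without hardware logs.

## The model in brief

ADC decode, Hall transfer and the on-axis ring field:

    V  = Vdd * c / (2^10 - 1)
    V  = S * B + Vdd / 2                      (clipped to [0, Vdd])
    B(x) = (Br/2) [ (x+T)/sqrt(Ro^2+(x+T)^2) - x/sqrt(Ro^2+x^2)
                  - (x+T)/sqrt(Ri^2+(x+T)^2) + x/sqrt(Ri^2+x^2) ]
    leg gap = x + T + W_sensor+board

`B(x)` decays monotonically beyond its near-face peak, so the distance `x`
is recovered by bisection on that branch (tolerance 1e-6 cm). Mid-stance
peaks are local maxima at least 0.8 s apart (a 150 steps/min cadence
ceiling) that pass a prominence filter; strides/min for stride *n* is
`60/(t_n − t_{n−1})` and cadence is twice that. Groups are screened with
Lilliefors normality and skewness/kurtosis, optionally cleansed with the
1.5×IQR rule, and compared against normal gait with Kruskal–Wallis
(medians) and Levene (variability) tests at α = 0.05. See
`vignettes/hall-gait-monitoring.Rmd` for the full account, including why
the default magnet constants are what they are.

## Worked example

Simulate one subject's normal-gait segment, process it, and summarize:

```r
library(hallgait)
m <- ring_magnet(); s <- hall_sensor(); g <- mount_geometry()

p <- stride_type_params("Normal", cadence_mean = 120, cadence_sd = 2,
                        leg_gap_mean = 1.53, leg_gap_sd = 0.046,
                        leg_gap_skew = -0.24, n_strides = 37)
sim <- simulate_trace(p, simulation_config(seed = 42), m, s, g)
sim$trace
#> <sensor_trace> 9503 samples over 38.0 s, codes 508..693

ser <- process_trace(sim$trace, m, s, g)
ser
#> <stride_series> 37 peaks (2 dropped by prominence, 1 out of range)
mean(ser$peaks$leg_gap, na.rm = TRUE)   # cm;  generator truth: 1.53
#> [1] 1.525
mean(ser$cadence$cadence)               # steps/min; generator truth: 120
#> [1] 120.0

describe_group(ser$peaks$leg_gap[ser$peaks$in_range])
#> # A tibble: 1 × 9
#>       n  mean     sd    iqr   max   min skewness kurtosis normal
#>   <int> <dbl>  <dbl>  <dbl> <dbl> <dbl>    <dbl>    <dbl> <lgl>
#> 1    36  1.52 0.0476 0.0756  1.62  1.41   -0.300     2.59 TRUE
```

All 37 injected strides are found (two noise bumps were rejected by the
prominence filter; one stride's peak read past the field maximum and is
flagged out of range), the recovered leg-gap mean is within one
quantization step of the generator's 1.53 cm, and cadence is recovered
exactly. The full cohort analysis — 4 subjects × 5 stride types, compared
per subject against normal gait — is one call:

```r
an <- run_gait_analysis(seed = 1)
an$detection
#> # A tibble: 5 × 4
#>   criterion           n_comparisons n_significant accuracy_pct
#> 1 gap_median                     16             9           56
#> 2 gap_variability                16             7           44
#> 3 union                          16            11           69
#> 4 cadence_median                 16            13           81
#> 5 cadence_variability            16             7           44
```

Each row is one detection criterion: the share of the 16 subject ×
stride-type comparisons flagged significantly different from normal gait
(leg-gap median and variability after outlier removal, their union, and
the two cadence criteria).

Instrument calibration figures for the default sensor–magnet pair:

```r
estimate_precision(m, s, 1)   # mm of distance per ADC state at x = 1 cm
#> [1] 0.0866
estimate_range(m, s)          # usable range, cm
#> [1] 3.52
```

A command-line front end with `simulate`, `process`, `compare` and
`report` subcommands lives at `inst/cli/gaitmon.R`.

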