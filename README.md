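# flapturb

**Turbulence effects on flapping flight, from raw biologger streams.**

Atmospheric turbulence forces flapping fliers to stabilise themselves — but
does a bird shift its *mean* wingbeat kinematics, or make *stroke-to-stroke*
corrections that show up as kinematic variability? `flapturb` answers this
for the standard homing-pigeon biologging setup (tri-axial acceleration at
200 Hz, barometric pressure at 20 Hz, GPS at 1 Hz, hourly reanalysis wind, a
terrain grid) by chaining:

1. **Wingbeat detection** — smooth the heave (dorsoventral) acceleration over
   20 samples, difference over 20 samples, mark positive-to-negative
   transitions of the differential, prominence-filter false peaks; per beat,
   frequency = 1/period between consecutive peaks and amplitude =
   peak-to-trough raw heave within the cycle (g). Flapping wing speed =
   mean frequency × mean amplitude (g·Hz), a propulsive-effort proxy.
2. **Turbulence proxy** — per 15 s flight segment, the interquartile range of
   linearly detrended barometric-pressure fluctuations (hPa); plus the
   Deardorff convective scale *w\** = (g·zi·Q0v/θv)^⅓ and friction velocity
   *u\** = √(|τ|/ρ) for climatological context, and a fixed-slope −5/3
   inertial-subrange fit `S(f) = A·f^(−5/3)` for anemometer records.
3. **Flight path** — ISA hypsometric altitude from 2 s-smoothed pressure
   (sea-level reference factored in), climb rate Vz from 1 Hz-resampled
   altitude, AGL via bilinear terrain sampling, great-circle headings,
   turning angles in (−180°, 180°], circular SD √(−2 ln R) as tortuosity,
   and wind-triangle airspeed / headwind component (hwc = −wind·t̂,
   positive into a headwind).
4. **Effect models** — eight per-segment responses (mean altitude AGL,
   tortuosity, mean and SD of wingbeat frequency, amplitude, airspeed), each
   fitted as `response ~ s(√turbulence) + s(hwc) [+ s(climb) + s(√AGL)] +
   (1 | flight)` with shrinkage smooths (mgcv, REML). Effect sizes are the
   centred partial effect of turbulence at its observed minimum and maximum,
   as a percentage of the response's observed range.

A synthetic-flight generator with full ground truth (per-segment turbulence
level, per-beat kinematics, true altitude, wind) makes every stage testable
without any field download.

## Worked example

Simulate four flights across a turbulence ladder T ∈ {0, 0.5, 1, 2, 3}, run
the full pipeline, and fit the sub-models:

```r
library(flapturb)
library(dplyr)

terrain <- terrain_grid(seq(8.5, 9.7, by = 0.05), seq(47.4, 48.3, by = 0.05),
                        matrix(400, 25, 19))
wind <- wind_series(c(0, 3600), c(2, 2), c(1, 1))

flights <- lapply(1:4, function(i) {
  simulate_flight(sim_config(duration = 300,
                             turbulence = rep(c(0, 0.5, 1, 2, 3), 4),
                             seed = i, flight_id = paste0("flight-", i)))$flight
})
segments <- analyze_flights(flights, terrain = terrain, wind = wind)
segments %>% select(flight_id, segment_id, wb_freq_mean, wb_freq_sd,
                    wb_amp_mean, wb_amp_sd)
#> # A tibble: 80 × 6
#>   flight_id segment_id wb_freq_mean wb_freq_sd wb_amp_mean wb_amp_sd
#>   <chr>          <int>        <dbl>      <dbl>       <dbl>     <dbl>
#> 1 flight-1           1         5.99     0.0410        4.01     0.101
#> 2 flight-1           2         5.99     0.116         3.93     0.329
#> 3 flight-1           3         6.03     0.190         4.01     0.505
#> 4 flight-1           4         6.04     0.414         3.98     0.824
#> # ℹ 76 more rows
```

Segment 1 was flown at T = 0 and segment 4 at T = 2: the mean frequency stays
at 6 Hz while its SD grows tenfold — stroke-to-stroke compensation, not a
mean shift. Fitting one sub-model:

```r
fit <- fit_response_model(segments, "wb_freq_sd")
fit
#> <flap_fit> wb_freq_sd ~ sqrt_turbulence + hwc + climb_rate + sqrt_altitude_agl + (1 | flight)
#>   n = 80, deviance explained = 89.6%, residual AR(1) = 0.03
tidy(fit)
#> # A tibble: 5 × 5
#>   term                       edf ref_df    statistic  p.value
#> 1 s(sqrt_turbulence)   3.29           9 35.7         0
#> 2 s(hwc)               4.05           9  2.30        0.000680
#> 3 s(climb_rate)        0.0000818      9  0.00000713  0.371
#> 4 s(sqrt_altitude_agl) 0.0000350      9  0.000000444 0.741
#> 5 s(flight_id)         1.82           3  1.53        0.0605
```

The turbulence smooth carries the signal; the null covariates shrink to
edf ≈ 0. The effect-size table across all eight sub-models (percent of each
response's observed range, at the observed turbulence minimum and maximum):

```r
effect_table(fit_flight_models(segments))
#>        response response_range pct_at_min pct_at_max
#> 1  altitude_agl         15.131       2.01      -2.48
#> 2    tortuosity          7.782     -13.3       16.8
#> 3  wb_freq_mean          0.216      -0.87       1.06
#> 4   wb_amp_mean          0.371      -0.00       0.00
#> 5 airspeed_mean          3.175      -0.43       0.53
#> 6    wb_freq_sd          0.674     -29.2       44.6
#> 7     wb_amp_sd          1.390     -34.2       52.1
#> 8   airspeed_sd          1.978     -10.9       14.0
```

The generator put its turbulence response only in the per-beat variability,
and the fitted table recovers exactly that structure: large positive effects
on the kinematic SDs and airspeed SD, near-zero effects on the means.
`autoplot()` methods exist for wingbeat series, segment tables, fits and
effect tables.

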