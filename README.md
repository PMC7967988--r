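# migratimer

Tools for analysing the **timing of migration in GPS-tagged shorebirds**
that winter at a fixed site — built around the kind of multi-year
biologging dataset produced by solar GPS/GSM loggers on Eurasian curlews
(*Numenius arquata*) wintering in the Wadden Sea and breeding in Arctic and
sub-Arctic Russia. The package is aimed at movement ecologists who have
Movebank-style fix tables and local weather-station records and want to ask:
*when* do individual birds leave and return, *what* drives that decision
(weather, breeding-site geography, or an internal clock), and *how
repeatable* is each individual's schedule across years?

## What it computes

* **Event detection** — departure from and arrival at the wintering site,
  per individual-year, from raw fixes: a departure is the first instant with
  ground speed above a sustained-flight threshold (default 20 km/h over
  ≥ 30 min) whose displacement from the wintering centroid grows
  monotonically past the 30-km relocation radius; arrivals mirror this with
  displacement shrinking below the residency radius.
* **Site classification** — wintering, stop-over and breeding residencies
  from gap-limited spatial clusters; the breeding site is the cluster
  farthest from the wintering centroid with a multi-week, non-directional
  stay.
* **Track metrics** — great-circle (haversine, R = 6371 km) and flown
  distances, flight time, first-stop duration, and track curvature
  `100·(flown − linear)/flown` for bouts logged at ≤ 5-min intervals.
* **Weather predictors** — sunrise-to-sunset means of eight 1-min station
  variables (circular mean for wind direction), a GAM-based cloudiness proxy
  from global radiation, 24-h means of four large-scale variables, and
  quotient contrasts of the event day against the previous day and the
  same-date mean of the four preceding years (difference fallback when the
  reference is exactly zero).
* **Wind support** — the tailwind component `TWC = v · cos x`, with `x` the
  angle between the tailwind direction (opposite the flight direction) and
  the meteorological wind direction; flight speed and altitude responses to
  TWC are fitted as mixed models.
* **Driver screen** — a 38-column predictor matrix (24 weather contrasts,
  2 TWC contrasts, 12 bird/track constants) screened with cross-validated
  LASSO (1-SE rule, folds blocked by individual), then confirmed in a linear
  mixed model of day-of-year with a random intercept per individual;
  predictors count as drivers only at the alpha-corrected *p* < 0.01.
* **Repeatability** — individually-standardised mean absolute differences of
  departure/arrival days and flight directions between consecutive tracked
  years, and a first-year-vs-subsequent-years mixed regression.
* **Synthetic ground truth** — `sim_config()` / `simulate_tracks()` /
  `simulate_weather()` generate multi-year tracks and weather with planted
  departure-day effects, wind-support responses and repeatability, so every
  stage of the pipeline can be validated against known truth.

## Worked example

```r
library(migratimer)

sim <- sim_config(n_individuals = 23, years = 2016:2018)
cfg <- pipeline_config(sim = sim, seed = 11)
res <- run_pipeline(cfg)
#> events: 29 departures, 23 arrivals
#> sites: 150 (29 breeding)
#> predictor matrix: 29 x 38 (0 rows dropped)
#> drivers: 4 selected, 2 significant at p < 0.01

res$drivers
#> Confirmatory mixed model (n = 29, random intercept per individual)
#>                     term estimate std_error t_value  p_value significant
#> 1 four_year_large_wind_v    0.861     0.614    1.40 1.72e-01       FALSE
#> 2          time_of_day_h   -1.124     0.598   -1.88 7.07e-02       FALSE
#> 3           breeding_lat    3.852     0.734    5.25 1.41e-05        TRUE
#> 4     linear_distance_km    6.604     0.798    8.27 5.27e-09        TRUE
#> significance threshold: p < 0.01
```

Out of 38 candidate predictors (most of them weather contrasts that are
noise by construction in the simulation), the screen retains four and the
confirmatory mixed model flags exactly the two planted drivers: birds
breeding **farther away** depart about 6.6 days later per standard deviation
of migration distance, and birds breeding at **higher latitudes** about
3.9 days later per SD of latitude — the geography-of-breeding signal the
pipeline is designed to isolate from weather. The repeatability table of the
same run shows consecutive-year departure days differing by 2.5 days on
average and departure directions by under 2 degrees:

```r
res$repeatability
#>   mean_abs_diff sd_abs_diff n_pairs n_individuals              metric
#> 1          2.50        1.52       6             6       departure_day
#> 2          2.25        2.50       4             4         arrival_day
#> 3          1.97        1.57       6             6 departure_direction
```

`tidy()`, `glance()` and `autoplot()` methods work on the fitted objects
(`lasso_screen`, `driver_fit`), and `plot_event_phenology()` draws the
departure/arrival histogram.

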