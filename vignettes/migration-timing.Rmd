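---
title: "Detecting, explaining and replaying migration timing with migratimer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting, explaining and replaying migration timing with migratimer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

migratimer analyses when GPS-tagged shorebirds leave and return to a shared
wintering site, what explains the variation in those dates, and how
repeatable each individual's schedule is. This vignette is the package's
account of the methods: the detection rules and their thresholds, the
weather-predictor construction, the two-stage driver screen, the
repeatability statistics, and the synthetic data generator that underwrites
the test suite — including the places where the design was genuinely open
and what we chose.

## The data model

The raw input is a Movebank-flavoured fix table: one row per GPS fix with an
individual identifier, a UTC timestamp, WGS84 coordinates, Doppler ground
speed and (for some devices) altitude above mean sea level. Devices log at
pre-programmed intervals of 1–15 min, densest inside a "geofence" corridor
near the wintering site. Ground speed is carried in km/h internally and
converted to m/s only at the Movebank CSV boundary. Weather comes in two
tables: a 1-min local station record (temperature, wind speed, maximum wind
speed, wind direction, precipitation, global radiation, air pressure,
humidity) and a daily large-scale table (temperature, pressure, u/v surface
wind components per grid cell).

A note on wind conventions: wind direction is meteorological throughout —
the compass bearing the wind blows *from*. The large-scale components use
the standard reanalysis convention, u = eastward and v = northward, so a
wind from 270° has u = +speed, v = 0. Source descriptions of such data are
not always consistent about which letter is which; we implement the
standard convention and say so here rather than silently matching any one
label.

## Event detection

Migration departure is visible in a track as an abrupt, sustained rise in
ground speed with monotonically growing displacement. We operationalise
"clear increase in flight speed" as ground speed above 20 km/h sustained
for at least 30 min (`speed_threshold`, `sustain_min`), and require net
displacement from the wintering centroid to pass 30 km
(`relocation_radius_km`) within 6 h. The 20 km/h threshold separates
powered flight from tidal roost shifts (typically < 5 km/h) by a wide
margin on both sides; all thresholds are configuration, not constants,
because the field protocol leaves the exact speed criterion open.

Two subtleties:

* Birds sometimes relocate within the wintering area shortly before
  departing — always under 30 km. Such bouts fail the displacement gate and
  are never scored as departures; the true departure is then detected from
  the relocation site. Because a departure from a relocation site can
  initially head back *towards* the wintering centroid, the monotonicity
  check applies from the displacement minimum onward, not from the bout
  start.
* Arrivals mirror departures: the first crossing into the 30-km residency
  radius after at least 24 h away, arrived at in sustained flight, and
  followed by at least 24 h inside. The event instant is the crossing,
  which also defines "arrival" in the synthetic ground truth so that
  detector and generator agree about what the arrival time *is*.

Both detectors return a typed absence — a zero-row events table — rather
than an error when no qualifying bout exists (stationary bird, transmitter
death en route).

## Sites, distances, curvature

Residency sites are built by time-ordered clustering: a fix joins the
current cluster while it is within 30 km (`cluster_radius_km`) of the
cluster's running centroid. The breeding site is the cluster that is
farthest from the wintering centroid *among* clusters with a stay of at
least 21 days (`breeding_min_stay_d`) and a straightness index (net
displacement over path length) below 0.3; the distance rule dominates among
qualifying clusters. Twenty-one days is deliberately conservative: observed
breeding stays run 47–62 days, so halving the minimum loses nothing and
tolerates partial residencies. If no cluster qualifies the result carries
an explicit `breeding_unresolved` attribute — never a silent zero and never
two breeding sites.

Distances are haversine great circles on a 6371-km sphere. Over the
European flyway (50–70°N, 5°W–65°E) ellipsoidal geodesics differ by at most
about 0.4%, far below any threshold used, and the tests hold the
implementation to 0.5% against an independent geodesic oracle. Track
curvature is `100·(flown − linear)/flown`; flown is the denominator (the
printed field values are consistent with that reading, which we flag as an
interpretation). Only bouts with every inter-fix gap ≤ 5 min are evaluable,
keeping flown distances comparable across devices. The flown path of the
first migration bout is anchored at the wintering and stop-over centroids
so that flown ≥ linear holds exactly by the triangle inequality.

## Weather predictors

Local station variables are averaged from sunrise to sunset of the event
day (NOAA solar-position equations, zenith 90.833°; latitudes poleward of
66.5° are refused because the daylight window is undefined there). Wind
direction is averaged as the direction of the circular resultant; a zero
resultant is "not evaluable". Large-scale variables are 24-h daily means.

Each event-day value is contrasted with two references: the previous day,
and the mean over the same calendar date of the four preceding years
(29 February references map to 28 February). Contrasts are quotients; when
the reference is *exactly* zero — precipitation means on dry days are exact
zeros, not small numbers — the difference is used instead and flagged. The
zero test is exact equality on purpose: an epsilon would misclassify
genuinely tiny means. That yields 8 local × 2 + 4 large-scale × 2 = 24
weather contrasts, plus two contrasts of the event-day tailwind component
against the same two references. Which wind feeds the two TWC variants is
not fully pinned down by the field protocol; we use local station wind for
both, with the two contrast references, and expose the choice.

The cloudiness proxy fits a penalized cubic regression spline of global
radiation on minutes-since-midnight (smoothness by GCV) over at least five
pooled cloudless days, then scores any day by the mean daylight deviation
of that clear-sky curve from the observations. Any smoother reproducing the
in-sample property (near-zero scores on training days) would do; mgcv's GAM
is the natural choice.

## The driver screen

One row per departure (or arrival) event, 38 predictors: the 24 weather
contrasts, 2 TWC contrasts, and 12 constants (number of migrations, sex,
catching location, year, time of day, breeding latitude, linear distance to
the breeding area, departure direction, time to first stop-over, duration
of first stop-over, flown and linear distance to the first stop).
Continuous columns are standardised to mean 0, SD 1 before penalisation;
sex and catching location enter as plain 0/1 dummies without group
penalisation (the simplest reading of the protocol). Rows with any missing
predictor are dropped and counted; fewer than 10 complete rows refuses to
fit.

Stage one is an L1-penalised linear regression over the whole matrix with
the penalty chosen by 5-fold cross-validation at the one-standard-error
rule. Folds are blocked by individual — all events of a bird share a fold —
so the CV respects the repeated-measures structure; fold assignment is
deterministic given the seed. Stage two refits the selected predictors
*jointly* (the alternative, one-at-a-time confirmation, is weaker against
correlated selections; the joint refit is our choice where the protocol is
silent) in a linear mixed model of day-of-year with a random intercept per
individual. Wald t statistics with an n − 1 degrees-of-freedom
approximation give p-values; because the predictors were pre-selected, only
terms with p < 0.01 count as drivers (alpha-inflation correction). A
singular random intercept falls back to the fixed-effects fit with a
warning. Day-of-year is treated as Gaussian by default — it is bounded and
roughly symmetric over a five-week window; the AIC comparison of Poisson,
negative-binomial and Tweedie mixed models is implemented
(`select_outcome_family()`, via glmmTMB) and exposed but not forced.

Reported degrees of freedom in field analyses of this kind are often
inconsistent across tests; we use the n − 1 approximation uniformly and
document it as an approximation rather than reproducing any particular
convention.

## Repeatability

"Individually-standardised mean absolute difference" is read as:
differences are computed within individuals (between consecutive tracked
years; a missing middle year breaks the chain) and then pooled. A z-scoring
variant — values centred and scaled within individual before differencing —
is available behind `standardize = "zscore"` since the phrase admits both
readings. Direction repeatability uses the shortest arc, so values live in
[0°, 180°]. `first_vs_subsequent()` regresses each later-year value on the
individual's first-year value with a random intercept, and reports the
fitted slope alongside its distance from the 1:1 line of perfect
repeatability.

## The synthetic generator

`simulate_tracks()` exists so that every stage above has an acceptance
surface with known truth. It emulates: multi-year wintering residency
scatter (< 5 km), optional pre-departure relocations under 30 km, an
evening departure (18:00–22:00 UTC, matching the observed diel pattern) on
a planted day-of-year, a first stop-over at about a third of the route, a
breeding residency of 47–62 days of non-directional scatter inside
55–70°N × 20–65°E, and a return leg with a nearer stop-over. Flight legs
are piecewise constant-velocity great circles with 50-m Gaussian jitter;
ground speed is `airspeed + gain·3.6·TWC` with the tailwind component from
the station wind at the nearest minute, and altitude rises 150 m per m/s of
headwind. There is no vertical wind shear, no landscape mask (tracks may
cross any terrain), and no mesoscale meteorology — the weather generator
produces plausible synoptic-scale day-to-day variability (AR(1) minute
noise around per-day regimes, exact-zero dry days, clear-sky radiation
curves scaled by a daily cloud factor), not reanalysis physics. Passing
tests therefore demonstrate that the pipeline recovers what it is designed
to recover under realistic noise, not that it is robust to every failure
mode of real biologging data (fix dropouts, Doppler speed outliers,
mid-flight weather fronts).

The planted departure model is
`base + beta_distance·(distance − 2339 km) + beta_latitude·(lat − 62.5°) +
individual intercept + noise`, kept continuous in the ground truth so that
regressing the latent day on distance and latitude with all noise SDs at
zero returns the planted slopes to machine precision. Defaults —
`base_departure_doy = 108`, `beta_distance = 0.01` d/km,
`beta_latitude = 1` d/degree, `sigma_individual = 3` d,
`sigma_noise = 2.5` d — were calibrated once against the printed field
ranges (departures spanning mid-April to mid-May over breeding distances of
roughly 1000–3840 km, consecutive-year departure differences of a few
days) and are the package's standing study conditions, not tuning knobs.
Two cadences are used: `fix_interval` (default 5 min) while airborne and
`residency_interval` (default 15 min, the devices' maximum programmed
interval) during residencies, mirroring the geofence/battery scheduling of
the real tags; gaps never exceed 15 min.

Determinism is per-date and per-track: every weather day and every
individual-year track is generated under its own seed derived from the
configuration seed, so a day simulated alone is byte-identical to the same
day inside a span, and reference windows years back are cheap.

Driver-screen validation replicates at the *event* level
(`simulate_driver_events()`): 80 departure events with the planted distance
and latitude effects, 24 weather contrasts and 2 TWC contrasts that are
pure noise around 1, and null first-stop predictors. Full fix-level
replication at 100 datasets × 80 events would cost hours for no additional
information about the screen itself; the fix-level path is exercised
separately by the event- and site-recovery studies (100 single-year tracks)
and the end-to-end pipeline run.

## Problem sizes and numerical choices

The shipped tests run the detectors on hand-built noise-free fixtures plus
simulated populations of 6–8 individuals; the acceptance checks use 100
single-year tracks for event/site recovery, 100 replicate 80-event datasets
for the driver screen, 10⁵ random inputs for the tailwind-component bound
and 10⁴ coordinate pairs for the distance oracle. These sizes were chosen
so the whole suite completes in a few minutes while keeping Monte-Carlo
error well inside the asserted margins.

Numerical details worth knowing: circular means return `NA` when the
resultant length falls below 1e-9; the contrast zero-test is exact; the
clustering centroid is updated incrementally (arithmetic mean of member
positions, matching the definition of a site centroid); LASSO runs on the
pre-standardised matrix with glmnet's internal standardisation off;
mixed-model singularities (including zero-residual degenerate fits, which
can fail only at the summary stage) fall back to ordinary least squares
with a warning, which also covers the one-observation-per-individual case
where the two coincide.

## Known limitations

* Detector thresholds are heuristics tuned for a tidal-flat wintering
  system; very short nonstop migrations (< 30 km) are undetectable by
  construction.
* Altitude-dependent outputs are `NA` when a device records no altitude;
  nothing is imputed.
* The repeatability module reports mean absolute differences, not a formal
  repeatability coefficient (ICC); that is a documented extension, not an
  output.
* No behavioural-state models (HMMs): the rules here are deterministic and
  auditable, which is the point, but they will not segment ambiguous tracks
  the way a fitted state model might.
* Real-data runs need a roster (sex, catching location) to fill the
  constant predictors; without one the driver matrix cannot be completed.
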