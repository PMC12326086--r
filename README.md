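# flocktrace

Flight and flocking dynamics of homing pigeons over heterogeneous
landscapes: a tested R pipeline from raw biologger streams to
habitat-conditioned linear mixed models.

## The problem

When a cluster flock of homing pigeons (*Columba livia domestica*) crosses
open fields, woodland and built-up areas on the way home, do the birds
change how hard they work (wingbeat frequency, a proxy for flight effort),
how fast they fly, and how tightly they flock? Answering this from field
data requires stitching together two asynchronous sensor streams per bird —
GPS at 5 Hz and dorsal z-axis accelerometry at 100 Hz — with a polygon map
of ground cover, reducing everything to aligned per-second records, and
then asking a model-selection machinery which habitat terms survive.

flocktrace packages that entire chain for movement ecologists:

* **Wingbeat extraction** — running-mean detrending, peak-interval
  frequency estimation over 15-sample windows, zero-phase Butterworth
  smoothing, per-second medians.
* **Trajectory processing** — local equirectangular projection, per-fix
  speed with a glitch ceiling, 200 m release/home trimming, flight-time and
  iteration indices.
* **Flock geometry** — cohesive membership (largest component of the 10 m
  proximity graph), robust centroid with iterative 40 m exclusion,
  stepwise direction of travel, absolute spread = along-travel extent +
  across-travel extent, signed front-back / left-right positions.
* **Habitat classification** — GeoJSON land-cover polygons grouped into
  open / wooded / urban, winding-number point-in-polygon with
  urban > wooded > open precedence and an open fallback.
* **Statistics** — per-second alignment and 15 s subsampling against
  autocorrelation, then for each response `y` (flap frequency, speed,
  spread, ...):

  `y ~ habitat + flight_time + iteration + habitat:flight_time +
  habitat:iteration + (1 | loft) + (1 | loft:bird)`

  with VIF pruning (threshold 5), exhaustive marginality-respecting subset
  search under ML, selection by ΔAIC < 2 → highest marginal r² → fewest
  terms, single-pass Cook's-distance outlier removal (4/n), and an REML
  coefficient report.
* **A flock-flight simulator** (`sim_config()`, `simulate_campaign()`)
  whose defaults encode the field design — 3 flocks of 6/10/8 birds, 15
  releases over a 9.58 km corridor, 17.92 m/s mean speed, 6.93 Hz mean flap
  frequency, habitat offsets on both — so every stage is verifiable by
  oracle equivalence and parameter recovery without any field download.

## Worked example

Simulate a scaled campaign (3 flocks x 2 flights), run the pipeline, and
look at the selected speed model:

```r
library(flocktrace)

cfg  <- sim_config(n_flights = 2, corridor_length_m = 4500,
                   gps_noise_sd = 0.2, accel_noise_sd = 0.05,
                   split_probability_per_min = 0, seed = 4)
camp <- simulate_campaign(cfg)
res  <- process_campaign(camp, validate_config(list(
          responses = c("flight_speed", "flap_frequency"))))

res$models$flight_speed
#> model_report: flight_speed
#>   selected: habitat + flight_time + iteration
#>   AIC = 1965.21, marginal r2 = 0.1697, n = 766, outliers removed = 42
#>          term   coefficient  estimate       se       F        p
#> 1 (Intercept)   (Intercept) 16.789030 0.441253      NA 2.95e-04
#> 2     habitat habitatwooded -0.613575 0.075581 137.453 1.98e-15
#> 3     habitat  habitaturban  0.656590 0.074239 137.453 6.71e-18
#> 4 flight_time   flight_time -0.000349 0.000435   0.647 4.22e-01
#> 5   iteration     iteration  0.198719 0.059787  11.048 9.32e-04

habitat_effects(res$models$flight_speed$final)
#>    level   estimate         se
#> 1 wooded -0.6136290 0.07537666
#> 2  urban  0.6565958 0.07403843
```

The injected ground truth for this campaign is a −0.7 m/s wooded and
+0.7 m/s urban speed offset relative to open ground; the selected model
recovers both within about one standard error, and the term-level F
statistic (137.5) is shared by the two habitat coefficients, as in standard
mixed-model ANOVA reporting. (At two flights the iteration term can soak up
between-flight chance variation, as here; the recovery experiments in the
test suite use five.) `habitat_effects()` reports the average
marginal habitat contrast — the coefficient plus any retained
habitat-by-covariate interaction evaluated at that habitat's mean covariate
value — which is the quantity to compare against an injected constant
offset.

Reference effect sizes from the published field study (urban flap −0.10 Hz
on a 6.93 Hz mean, i.e. a 1.44% change; speed ±0.7 m/s on 17.92 m/s, i.e.
~3.8%) ship with the package:

```r
unlist(habitat_effect_summary())
#>   urban_flap_pct_of_mean  urban_speed_pct_of_mean wooded_speed_pct_of_mean
#>                 1.443001                 3.850446                 3.738839
#>    urban_vs_wooded_speed                 n_flocks                  n_birds
#>                 1.360000                 3.000000                24.000000
#>               n_releases
#>                45.000000
```

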