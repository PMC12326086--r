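---
title: "Methods: from biologger streams to habitat-conditioned mixed models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from biologger streams to habitat-conditioned mixed models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

flocktrace implements an analysis pipeline for homing-pigeon flight and
flocking behaviour over heterogeneous landscapes: from raw 5 Hz GPS logs and
100 Hz dorsal z-axis accelerometry to per-second flap frequency, flight
speed, flock-geometry metrics and ground-cover labels, and from there to
habitat-conditioned linear mixed models selected by exhaustive AIC search.
This vignette documents the model, the tunable constants, the numerical
choices, what the bundled simulator does and does not emulate, and the known
limitations. Nothing here states an empirical result that the package's
tests and `scripts/acceptance.R` do not themselves compute.

## The measurement model

**Wingbeat (flap) frequency.** A flying pigeon's dorsal acceleration is,
to first order, gravity plus a near-sinusoidal wingbeat oscillation of a few
tenths of a g to ~2 g at 5-9 Hz, plus sensor noise and slow drift. The
pipeline removes gravity and drift with a subtracted centred running mean
(`detrend_z()`), detects wingbeat peaks on the detrended signal, converts
inter-peak intervals to instantaneous frequencies, summarises them over
consecutive 15-sample windows (`estimate_flap_frequency()`), low-pass
filters the window-rate series with a zero-phase Butterworth filter
(`butterworth_smooth()`), and aggregates to per-second medians.

Constants, with units and rationale:

* `detrend_window_s = 1` s (100 samples). Long against a ~0.14 s wingbeat
  period — the running mean attenuates a 7 Hz tone by well under 1% — and
  short against battery/temperature drift.
* `window_len = 15` samples (0.15 s), roughly one wingbeat. An interval
  overlapping a window contributes its instantaneous frequency to that
  window's mean.
* Peak threshold `prominence_factor = 0.3` times the 1 s rolling standard
  deviation of the detrended signal; peak times are refined by parabolic
  interpolation so the 100 Hz grid does not quantise inter-peak intervals.
  Without the refinement, a 7 Hz tone yields intervals of 14 or 15 samples
  and per-window estimates oscillate by ~0.2 Hz.
* Butterworth defaults: order 2, cutoff 1 Hz, applied forward-backward
  (zero phase, DC gain 1) to the ~6.7 Hz window-rate frequency series. This
  passes habitat-scale variation (tens of seconds) and removes estimator
  chatter. The filter is applied to the *frequency series*, not the raw
  acceleration: applying a 1 Hz low-pass to the raw signal would erase the
  wingbeat band itself.
* Missing data propagate: gaps are interpolated only transiently for the
  zero-phase filter and re-masked afterwards.

**Trajectory.** Fixes are projected onto a local equirectangular plane
about the home site: x = (lon − lon₀)·cos(lat₀)·111320, y = (lat −
lat₀)·111320 (metres). Over a < 10 km corridor at 51.5° N the error against
a great-circle oracle is below 0.1% and the transform is exactly
invertible, which is why no UTM dependency is used. Speed is per-fix
displacement over the time gap, with a 50 m/s plausibility ceiling (GPS
glitch guard, far above racing-pigeon speeds). All records within 200 m
(inclusive) of the release or home site are trimmed to exclude the atypical
circling flight at either end, and the retained time span also trims the
accelerometry.

**Flock geometry.** At each whole second, birds pairwise within 10 m are
linked and the largest connected component is the flock (chain connectivity
— the transitive reading of "within 10 m of each other"; components of size
one are not flocks). The centroid is the arithmetic mean of member
positions with iterative exclusion of members 40 m or further away, which
makes the larger subgroup dominate when a flock splits while letting
excluded birds reintegrate at later timestamps. The direction of travel is
the normalised stepwise centroid displacement; steps under 0.5 m carry the
previous heading forward (avoiding degenerate normalisation), and the
release-to-home unit vector seeds the first frame. Each member's position
decomposes into front-back (positive ahead) and left-right (positive to the
right of travel) components; absolute flock spread is the along-travel
extent plus the across-travel extent. A front-back tie (a bird exactly on
the centre line) counts as "front" — a deterministic, measure-zero choice.

**Habitat.** Land-cover polygons come from GeoJSON feature collections
whose fine class names are grouped into open, wooded, and urban; points in
no polygon are labelled open (mirroring the grouping of "Unclassified"
ground under open), overlaps resolve by urban > wooded > open (built-up
cover is the most specific label), and boundary points count as inside.
Containment is computed in geographic coordinates by a winding-number test
— projection-invariant at this extent — and is verified against an
independent ray-casting oracle in the tests.

**Alignment and subsampling.** All streams reduce to per-second medians
(positions component-wise) keyed by (bird, flight, second); records exist
only where GPS exists. Flock geometry is computed on the full per-second
series *before* subsampling. To blunt temporal autocorrelation, every 15th
second per bird and flight is retained, on a grid anchored at the flight's
first second and shared across the flock's birds so retained timestamps
match between flock members. The suite verifies that lag-1 autocorrelation
of an AR(1) series with coefficient 0.95 drops below 0.95^15 + 0.05 after
subsampling.

## The statistical model

Each response (flap frequency, absolute spread, distance to centroid,
group size, flight speed, front-back and left-right distance) is modelled
by linear mixed regression with random intercepts for loft and for bird
nested in loft. Absolute spread and distance to centroid are square-root
transformed. The stages are:

1. **VIF pruning**: main-effect terms with generalized VIF (scaled by
   degrees of freedom and squared, so continuous terms reduce to the plain
   VIF) above 5 are dropped iteratively, highest first; exact collinearity
   drops the later-ordered offender. Interactions are never VIF-tested
   against their own parents and follow their parents out.
2. **Exhaustive search**: every subset of the pruned terms respecting
   marginality (an interaction only with both parents) is fitted by maximum
   likelihood — ML, not REML, because AIC comparisons span different fixed
   structures. The search refuses model spaces beyond 2^14 specifications
   rather than silently subsampling them.
3. **Selection**: among fits within ΔAIC < 2 of the minimum, the highest
   marginal r² wins; r² ties at the fifth decimal go to the model with the
   fewest terms; any residual tie to the lowest AIC. Fits whose random-effect
   variance sits at the boundary (below 1e-8 of the residual variance) are
   singular and ineligible, as are non-convergent fits.
4. **Influence**: Cook's distances are computed in closed form from the
   fixed-effects projection (D = r²h/(p(1−h))), rows above 4/n are removed
   once (no iteration, keeping the procedure deterministic), and the model
   is refit. The closed form is oracle-tested against brute-force
   leave-one-out refits.
5. **Report**: the selected structure is refit by REML; the coefficient
   table carries estimates, standard errors, Satterthwaite term-level F
   statistics and coefficient p-values.

Marginal r² (variance of the fixed-effect predictions over the total
fixed + random + residual variance) is used because the selection compares
fixed structures; the conditional flavour would reward random-effect
variance that all candidates share. A multinomial-regression diagnostic
(`layer_independence_check()`) verifies that ground cover is not
collinear with bird or loft identity before those are used as random
effects.

`habitat_effects()` reports the average marginal contrast of each habitat
level against the reference: the habitat coefficient plus any retained
habitat-by-covariate interaction evaluated at that level's mean covariate
value. Because ground cover is laid out along the corridor, habitat and
flight time are partially collinear, and the raw main effect alone is
reference-point-dependent whenever an interaction is retained.

Default candidate terms are habitat, flight time, iteration and the two
habitat interactions (13 specifications under marginality). The full
"every calculated variable" candidate sets are supported through
`candidate_terms`, but the default keeps the per-response search tractable
and focused on the habitat question; covariate-adjusted runs are a
configuration choice, not a different code path.

## The simulator and what it emulates

`sim_config()` defaults encode the study design the pipeline targets:
three flocks of 6/10/8 birds, 15 homing flights each along a 9.58 km
release-to-home corridor (the release at 51.5001° N, −0.5842° E, home at
51.4154° N, −0.5726° E), GPS at 5 Hz, accelerometry at 100 Hz, mean flight
speed 17.92 m/s and mean flap frequency 6.93 Hz. Habitat acts additively on
the instantaneous speed (wooded −0.7, urban +0.7 m/s) and flap frequency
(wooded +0.03, urban −0.1 Hz). Behaviour is a correlated random walk with
homing bias and cohesion: each bird steers toward home, toward (or away
from) its flock centroid with a target spacing of 5 m scaled by per-habitat
spread multipliers, with AR(1) directional persistence and small heading
noise. The wingbeat phase is integrated continuously (a phase accumulator)
so frequency changes never create discontinuities in the synthetic
accelerometer signal, which is gravity + a 1 g wingbeat sinusoid + white
noise + a slow sinusoidal drift.

Values the study itself does not pin down were chosen once, on field
realism, and are documented here:

* Bird and loft intercepts: speed 1.0 / 1.0 m/s, flap 0.2 / 0.2 Hz.
  Individual cruising-speed differences of ~1-2 m/s and flap differences of
  a few tenths of a Hz (the scale implied by documented mass effects of
  ~0.1 Hz per 5 g) are typical; with only three lofts, a much smaller loft
  component would sit at the ML boundary in most fits and make every model
  singular, contrary to the result structure the simulator is meant to
  emulate.
* AR(1) wobble on instantaneous speed and flap: 0.8 m/s and 0.25 Hz
  (roughly 4% of the respective means), lag-0.2 s coefficient 0.9.
* GPS noise 1.5 m per fix (consumer-grade scatter); accelerometer noise
  0.1 g; drift 0.05 g at a 60 s period.
* Splits: with probability 0.05 per minute a minority subgroup (n/3)
  diverges at least 80 m laterally — beyond the 40 m exclusion radius, so
  the centroid-weighting rule is exercised — for 30 s before reintegrating.
* Station-keeping (`speed_match_ms`) defaults to 0. Enabling it makes
  birds hold station by adjusting speed (bounded, zero-mean within the
  flock), which transmits spacing changes — such as an injected
  iteration-by-iteration spread trend — crisply into measured spread, but
  it also makes each bird's realized speed track the flock's, hiding
  individual speed intercepts from the mixed models. The trend-recovery
  experiment enables it; the parameter-recovery experiments leave it off.

The simulator does **not** emulate wind or thermals, altitude, predator
events, route learning (routes are statistically identical across
iterations unless a trend is injected), sex or mass structure, or logger
dropouts. Passing recovery tests therefore show that the pipeline's
estimators are unbiased and appropriately calibrated *for data of this
structure*; they cannot certify behaviour under unmodelled field effects
such as wind-driven speed heterogeneity or systematic logger failure.

## Problem sizes used by the verification suite

The recovery experiments run scaled campaigns — 3 flocks × 5 flights over
the full corridor with reduced sensor noise (GPS 0.2 m, accelerometer
0.05 g) — ten seeded replicates, checking that each injected habitat effect
is recovered with the correct sign and within two standard errors in at
least 80% of replicates. Five flights rather than fifteen keeps a ten-
replicate experiment within a desk-scale run; the full corridor is
retained deliberately, because shortening it both reduces the number of
retained subsample points per flight (the 15 s grid then aliases against
the fixed habitat bands) and raises the fraction of boundary-mixed seconds,
each of which biases habitat contrasts noticeably at shorter corridor
lengths. Geometry and classifier oracles run on 10³-10⁴ random instances;
signal-recovery checks use 10-60 s synthetic tones.

## Degenerate inputs and tie-breaks

Flat accelerometer signals yield all-missing flap series (flagged, not an
error); seconds with fewer than two cohesive birds yield individual records
but no flock frame; a flight fully inside a trim disc yields an empty-flight
warning; duplicate GPS timestamps keep the first fix; out-of-order
accelerometry is sorted with a warning; the front/back tie at exactly zero
front-back distance goes to front; equal-size cohesive components tie-break
toward the previous centroid (or the release-home axis on the first frame).
Sqrt transforms refuse negative input rather than producing NaN.

## Known limitations

* Mixed-model influence is approximated through the fixed-effects hat
  matrix; exact mixed-model case deletion differs when random-effect
  shrinkage is strong. The approximation is oracle-exact in the
  fixed-effects limit, which the tests pin down.
* The front-back/left-right models are expected to be singular on data of
  this design (bird-level variance in signed station is near zero); the
  pipeline reports the flag and stops for those responses rather than
  degrading the random structure.
* Habitat labels at habitat boundaries are single-label summaries of mixed
  seconds; contrasts attenuate by roughly the boundary-second fraction
  (about 2-3% on the full corridor).
* The classifier assumes WGS84 inputs and polygonal (not raster) cover.
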