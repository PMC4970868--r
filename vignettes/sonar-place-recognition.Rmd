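---
title: "Template-based place recognition with batlike sonar: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Template-based place recognition with batlike sonar}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(echoplace)
```

## The hypothesis being modelled

Echolocating bats navigate to remembered places, but a cruising bat almost
certainly cannot reconstruct the 3D layout of a cluttered scene from its
echoes: temporal integration in the auditory periphery (~200 µs) fuses every
echo arriving from a shell of space whose volume grows rapidly with distance
(`integration_volume()`; about 1 m³ at 7.8 m for a 45° beam), and the
spectral cues that encode object identity are confounded with the cues that
encode position. An alternative is *template-based* place recognition: the
bat stores the low-dimensional cochlear signature of the echo train heard at
a place and gaze direction, and recognises places by matching incoming
signatures against that library — the acoustic analogue of the snapshot
model of insect visual homing.

Two properties make such signatures usable, and this package quantifies
both on synthetic ensonification data:

1. **Classifiability** — a noisy re-observation of a template must be
   assignable to the right template (probability of correct classification,
   `P_c`).
2. **Continuity** — template dissimilarity must grow monotonically with
   spatial or angular displacement over a non-trivial range (the *catchment*
   of the template), so a bat slightly off the remembered pose still
   descends the right gradient.

## Forward model: scenes and echo trains

Scenes are collections of ideal point reflectors (`generate_scene()`,
`boulder_corridor()`, `vegetation_corridor()`). An echo train is synthesized
(`synthesize_echo_train()`) as

* the saturated pickup of the emitted call at time 0 (the emission overloads
  the microphones; its exact clipped shape is irrelevant because templates
  blank the first 5.8 ms),
* plus, for each reflector at range $r$: a copy of the call delayed by
  $2r/c$ and scaled by $\mathrm{strength} \times g(\theta) / r^2$ — two-way
  spherical spreading with the emission beam gain $g$ evaluated at the
  offset $\theta$ from boresight,
* plus white Gaussian device self-noise.

The call is a 1 ms hyperbolic (linear-period) FM sweep from 100 to 40 kHz
with 5% cosine tapers; recordings last 34 ms at 219 kS/s (7446 samples), so
the sonar horizon is 5.83 m. The beam is a Gaussian taper with a two-sided
3 dB opening angle of 20° at 55 kHz, scaling inversely with frequency; in
synthesis it is applied as a scalar at the reference frequency, which is
adequate because the templates average out frequency anyway. Reflectors are
ideal points — extended objects are seeded clusters of points — because the
template pipeline only needs realistic delay/amplitude structure, not
surface physics. Atmospheric absorption and ground reflections are not
modelled. The speed of sound defaults to 343 m/s (20 °C air) and is
configurable.

The canonical device (`device_spec()`) records 31 microphones (a planar
array within 5 cm; inter-microphone differences are second order because
templates average across microphones), 3 repeats per gaze direction, and a
pan-tilt grid of 31 azimuths (−150°..150°, 10° steps) × 7 elevations
(−25°..39.8°, 10.8° steps) = 217 directions. One position therefore yields
217 × 31 × 3 = 20,181 echo trains.

## The template pipeline

`build_templates()` / `simulate_position_templates()` implement, per echo
train and position:

1. **Auditory periphery** (`cochleogram()`): a gammatone filterbank with 15
   centre frequencies (30–100 kHz, 5 kHz steps), half-wave rectification,
   power-law compression with exponent 0.4, and a 1 kHz second-order
   (12 dB/octave) Butterworth low-pass. The gammatone channels are 4th-order
   all-pole cascades with ERB-scaled bandwidths (b = 1.019·ERB); order and
   bandwidth are exposed as configuration since the periphery family this
   follows does not pin them down, and 4/1.019·ERB are the standard choices.
   The low-pass can undershoot slightly on transients, so activations are
   clamped at zero; clamping preserves the $a^{0.4}$ homogeneity of the
   stage.
2. **Dechirping** (`dechirp()`): each channel is shifted in time so the
   per-channel maximum (the saturated call pickup) aligns across channels;
   the alignment target is the earliest channel argmax, so shifts are
   non-negative and only end-padding with zeros is needed. Ties break to the
   earliest index; silent channels stay put with a warning. This removes the
   sweep's delay structure, standing in for channel-wise autocorrelation
   with the (unavailable, saturated) call pickup.
3. **Onset blanking** (`blank_onset()`): samples earlier than 5.8 ms
   (≈1 m two-way) are zeroed — 1271 samples at 219 kS/s; 1270.2 is rounded
   outward to be conservative about call contamination. Blanking follows
   dechirping, matching the stage order of the construction procedure.
4. **Collapse** (`collapse()`): unweighted mean over the 15 frequency
   channels and all microphones per (direction, repeat) — 651 raw profiles
   per canonical position. Templates deliberately carry no spectral
   information.
5. **Neighbourhood averaging** (`spatial_average()`): each direction's
   profile is replaced by the mean over its 3×3 grid neighbourhood
   (truncated at edges; the −150..150° azimuth range does not wrap). This
   widens the narrow emitter beam into a batlike virtual beam.
6. **Temporal integration** (`downsample_profile()`): means over 350 µs
   bins, trailing partial bin discarded — 97 samples per template
   (1/350 µs = 2.857 kHz; the interval, not its rounded rate, is treated as
   authoritative). Bin means rather than decimation: the signal is already
   1 kHz-limited and bin means are the natural reading of a temporal
   integration interval.
7. **Repeat averaging**: mean over the 3 repeats, after the spatial
   average, per the stage order of the construction procedure (both stages
   are linear so the order does not change the value, only the bookkeeping).

A fused C++ path (cochleogram → dechirp → blank → channel mean per echo
train) makes a full canonical position run in about two minutes in bounded
memory; a test asserts it equals the composed R stages to 1e-12.

## Noise model and classification

Templates carry two kinds of noise (`calibrate_noise_model()`):

* **Noise floor `n_f`** — the maximum template value over reflector-free
  runs (`noise_floor_from_device()`, three panoramic runs by default);
  stored templates are floored at `n_f` (`apply_floor()`), since smaller
  values encode nothing but the absence of echoes.
* **Perceptual noise `sigma_n²`** — i.i.d. Gaussian noise on each of the 97
  template samples, calibrated so two single-echo templates differing by
  2 dB in echo intensity (a conservative just-noticeable difference for
  echolocators) are discriminated at 75% correct. For two templates at
  Mahalanobis distance $d$ the two-alternative correct rate is
  $\Phi(d/2)$, giving the closed form
  $\sigma_n = \lVert\Delta T\rVert / (2\,\Phi^{-1}(0.75))$, verified by
  Monte Carlo. The calibration echo is a boresight point reflector at 2 m,
  synthesized noiselessly and processed by the full pipeline; the choice of
  range is configuration — the closed-form property holds regardless. One
  global `sigma_n²` is used for all positions and sites.

`classify_prob()` estimates $P_c(i)$ by Monte Carlo: draw
$T_i' = T_i + \mathcal N(0, \sigma_n^2 I)$, assign each draw to the nearest
stored template by Mahalanobis distance (with $Q = \sigma_n^2 I$ this is
Euclidean distance over $\sigma_n$), and report the fraction assigned to
$i$ plus the full assignment distribution. Draws are evaluated in blocks of
50; estimation stops when the running estimate changes by less than 0.01
between checks, bounded between 100 and 1000 replications. Exact distance
ties — common when floored templates coincide — break uniformly at random,
which symmetry demands (N identical templates each get $P_c \approx 1/N$).
Noisy draws are *not* re-floored: the floor models the device, the Gaussian
noise the perceiving brain; a configuration switch restores re-flooring.
The expected angular error (`angular_error()`) weights the great-circle
separation between the true and assigned gaze directions by the assignment
distribution; confusions with other positions' templates contribute through
their own direction labels. `cross_position_confusion()` measures the drop
in $P_c$ when the candidate pool grows from one position's panorama to the
whole library.

## Catchment analysis

`median_pairwise_dissimilarity()` supplies the normalizer $M$. A
dissimilarity-vs-separation curve starting at (0, 0) is scanned outward
(`monotone_run_length()`): the run survives dips smaller than 1% of $M$
(allowing for noise), and the catchment is the largest separation inside
the run whose dissimilarity reached at least 10% of $M$ (so trivial
increases never count); it is 0 if that level is never reached.

* **Angular** (`angular_catchment()`): all template pairs of one position,
  great-circle separation binned at 10° (the azimuth step; the az/el grid
  makes separations continuous, so binning is needed before averaging). A
  bin's separation coordinate is the largest separation attained in it,
  which makes the catchment reading invariant to bin width for monotone
  curves. The 1%/10% rules are applied here too for consistency (they were
  introduced for the linear case); strictness is a configuration flag.
* **Linear** (`linear_catchment()`): per direction and transect position,
  dissimilarity versus $|\Delta x|$, averaging the two transect directions
  where both exist; endpoint positions contribute one-sided curves as-is.
  The per-direction summary is the median catchment over positions. The
  run length is computed per (position, direction) and then summarised —
  the reading of "average distance over which dissimilarity increases"
  that matches the per-direction median summary.

`tradeoff_report()` pools per-template $P_c$ and linear catchment and
computes the Spearman rank correlation plus Wilcoxon rank-sum comparisons
between the two corridors; a constant-$P_c$ input yields an explicit
not-applicable marker instead of a correlation.

## The synthetic study designs and their scales

The shipped configurations mirror the three field campaigns:

* `spots_study_config()` — 12 isolated positions: 4 open (no reflector in
  range), 4 semi-cluttered (Poisson scatterers at 0.05 m⁻³), 4 cluttered
  (0.4 m⁻³), in a 12 × 12 × 6 m box around the device. Densities were
  chosen once so that a cluttered position has a few hundred scatterers
  within the 5.8 m horizon — several per beam — and a semi-cluttered one a
  few tens.
* `transect_study_config("boulders")` — a corridor lined with strong
  (strength 3), compact rock clusters (12-point Gaussian clusters,
  SD 0.3 m) spaced ~1.5 m along walls 3 m from the line. The wall distance
  keeps the whole wall within the recording horizon while maximising the
  distance contrast with the vegetation corridor.
* `transect_study_config("vegetation")` — the same corridor lined instead
  with dense weak foliage points (40 m⁻¹ per side, strength 0.5 lognormal)
  0.8–1.8 m from the line. Foliage strength was set so near-foliage echo
  amplitudes are comparable to the 2 dB-calibration echo, making the
  near-reflector site the highly-classifiable one.

At `scale = "full"` these use the canonical device and the surveyed designs
(50 positions × 20 cm and 40 × 25 cm). The `scale = "scaled"` variants used
by the tests and the analysis scripts shrink only what does not carry the
mechanism: the spots design keeps the full 217-direction grid (the chance
level 1/217 is the quantity of interest) but uses 2 microphones; the
transects keep the 10° azimuth step and the 10.8° elevation step — with the
3×3 averaging these set how confusable adjacent gaze directions are, which
drives the classification/continuity trade-off — and the sub-beam per-step
parallax (25 cm spacing against a 3 m wall), but use 19 azimuths × 3
elevations, 12 positions and 2 microphones. Fewer microphones only shallow
the noise averaging; one microphone was rejected because the extra template
noise breaks the shallow monotone runs of the boulder curves.

What the generator does *not* emulate: extended rough surfaces, ground and
multipath, atmospheric absorption, wind and transducer directivity ripple,
and the full spectral beam structure. Passing tests on these scenes
therefore show that the pipeline and statistics behave as the theory
predicts on idealised point-scatterer fields — they do not certify
performance on field recordings.

## Numerical choices and degenerate inputs

* Echo delays are rounded to the nearest sample (350 µs bins make
  sub-sample alignment irrelevant); the delay oracle in the tests tolerates
  one sample.
* Dechirp argmax ties break to the earliest index; all-zero channels warn
  and stay unshifted; an all-zero cochleogram passes through unchanged.
* `calibrate_sigma()` rejects criteria outside (0.5, 1), where no finite
  positive solution exists; identical calibration templates are an error.
* Classification with duplicate templates is valid input; exact ties break
  uniformly at random under the seeded RNG.
* `monotone_run_length()` requires the curve to start at separation 0 with
  dissimilarity 0; `linear_catchment()` requires at least three transect
  positions; a singleton set has no median pairwise dissimilarity.
* All simulation entry points take integer seeds and are bit-reproducible;
  per-position seeds are derived from the study seed.

## Problem sizes used by the shipped analyses

The analysis scripts and the test suite run the scaled designs described
above: the spots study simulates 12 × 217 × 3 × 2 = 15,624 echo trains, a
corridor pair 2 × 12 × 57 × 3 × 2 = 8,208, and the noise calibration adds
three reflector-free panoramas plus two 9-direction calibration patches.
One full-device position (20,181 echo trains) is run end to end to verify
the canonical count contracts (20,181 → 651 → 217 at 97 samples each).

## Known limitations

* $P_c$ levels depend on the chosen reflector strengths relative to the
  calibration echo; the qualitative ordering across habitats is the robust
  output, not absolute values.
* The catchment statistic is quantised by the transect spacing and bounded
  by the transect length; scaled transects truncate catchments above ~2.75 m.
* The beam is applied as a scalar gain at 55 kHz rather than per frequency
  channel; spectrally structured beams would perturb the cochleogram before
  frequency averaging, an effect the templates discard by design but which
  could matter for other readouts.
* Real-data statistics from the field campaigns (mean catchments, site
  rank-sum Z values, pooled correlation magnitudes) depend on the original
  recordings and are out of scope here; the synthetic study reproduces the
  signs and orderings, not the magnitudes.
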