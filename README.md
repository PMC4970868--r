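# echoplace

Template-based place recognition with batlike sonar, on synthetic
ensonification data.

Echolocating bats remember and revisit places, yet their sonar almost
certainly cannot reconstruct the 3D layout of a cluttered scene: the
auditory system's ~200 µs temporal integration fuses all echoes arriving
from a shell of space whose volume reaches ~1 m³ at 7.8 m for a 45° beam.
`echoplace` implements and tests the alternative: a bat stores the
*cochlear template* of the echo train heard at a place and gaze direction —
a frequency- and microphone-averaged, dechirped, 350 µs-integrated profile,
97 samples long — and recognises places by nearest-template matching. The
package is aimed at computational bioacousticians and sensory ecologists
who want to probe when such echo signatures are (1) uniquely classifiable
and (2) spatially continuous.

## What it does

* **Scene and echo-train synthesis** — parametric habitats (open /
  semi-cluttered / cluttered Poisson scatterer fields; boulder-lined and
  vegetation-lined corridors) ensonified by an emulated panoramic device:
  1 ms hyperbolic FM call (100→40 kHz), 34 ms recordings at 219 kS/s, 31
  microphones, 217 gaze directions × 3 repeats per position.
* **Template construction** — gammatone filterbank (15 channels,
  30–100 kHz), rectification, `^0.4` compression, 1 kHz low-pass,
  dechirping, 5.8 ms onset blanking, averaging over frequencies and
  microphones, 3×3 direction-neighbourhood averaging, 350 µs temporal
  integration, repeat averaging: 20,181 echo trains → 651 profiles → 217
  templates per position.
* **Classifiability** — noise floor from reflector-free runs; Gaussian
  template noise σₙ calibrated so a 2 dB single-echo intensity difference
  is discriminated at 75% correct
  (σₙ = ‖ΔT‖ / (2 Φ⁻¹(0.75))); Monte-Carlo nearest-template
  classification (Mahalanobis distance, 100–1000 adaptive replications)
  giving per-template P꜀ and expected angular error.
* **Continuity** — angular and linear catchment distances: the separation
  range over which template dissimilarity rises monotonically (1%-of-median
  dip tolerance, 10%-of-median floor), plus the classifiability/continuity
  trade-off report (rank correlation, rank-sum site comparison).

## Worked example

Geometry of the problem, then a calibrated noise model:

```r
library(echoplace)

shell_thickness(200e-6, 343)     # 0.0343 m shell per echo sample
integration_volume(7.8, 45)      # 1.002 m^3 at 7.8 m, 45 degree beam
integration_volume(7.8, 60)      # 1.764 m^3 at 60 degrees

spec <- device_spec(n_mics = 2, mic_offsets = mic_array(2))
nm <- calibrate_noise_model(spec, rng_seed = 1)
```

The calibration prints (via `analysis/02_noise_calibration.R 1`):

```
noise floor n_f        = 0.0155534
||delta T|| (2 dB)     = 0.00772099
sigma_n (closed form)  = 0.00572358
MC correct rate (1e5)  = 0.7484  (criterion 0.75)
```

`n_f` is the largest template value the device produces with no reflector in
range — template samples below it carry no scene information and are floored.
`sigma_n` is the perceptual noise that makes a 2 dB louder copy of a single
2 m echo just discriminable (75% correct); the Monte-Carlo rate of 0.7484
over 2 × 10⁵ classified draws confirms the closed form.

The analysis workflow then runs the synthetic study:

```sh
Rscript analysis/01_integration_volume.R       # integration-volume table
Rscript analysis/02_noise_calibration.R 1      # noise model (above)
Rscript analysis/03_spots_experiment.R 1       # 12 positions x 3 clutter levels
Rscript analysis/04_corridor_tradeoff.R 10     # 10 matched corridor pairs
Rscript analysis/05_cross_position_confusion.R 1
```

`03` classifies every template within its position's panorama: open
habitats sit at chance (mean P꜀ ≈ 0.004 ≈ 1/217, all angular catchments 0)
while cluttered and semi-cluttered ones reach median P꜀ 0.93 (cluttered)
with angular catchments of 80–176°. `04` contrasts a corridor of strong distant boulders with one of
weak near foliage: boulders give larger median linear catchments, foliage
gives higher mean P꜀, and pooled P꜀ versus catchment is negatively rank
correlated — the motion-parallax trade-off. Tables land under `results/`.

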