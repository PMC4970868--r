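#' Hyperbolic FM call waveform
#'
#' Linear-period (hyperbolic) frequency-modulated sweep from `call_f0` to
#' `call_f1` kHz over `call_duration` seconds, with 5% raised-cosine tapers
#' at both ends to limit spectral splatter. The instantaneous frequency is
#' f(t) = f0 f1 T / (f1 T + (f0 - f1) t).
#'
#' @param spec a [device_spec()].
#' @return numeric vector of `round(call_duration * sample_rate)` samples,
#'   unit peak amplitude.
#' @export
call_waveform <- function(spec) {
  n <- round(spec$call_duration * spec$sample_rate)
  t <- (seq_len(n) - 1) / spec$sample_rate
  f0 <- spec$call_f0 * 1000
  f1 <- spec$call_f1 * 1000
  T <- spec$call_duration
  phase <- 2 * pi * f0 * f1 * T / (f0 - f1) * log1p((f0 - f1) * t / (f1 * T))
  w <- sin(phase)
  ntap <- max(1, round(0.05 * n))
  ramp <- 0.5 * (1 - cos(pi * (seq_len(ntap) - 1) / ntap))
  w[seq_len(ntap)] <- w[seq_len(ntap)] * ramp
  w[n + 1 - seq_len(ntap)] <- w[n + 1 - seq_len(ntap)] * ramp
  w
}

# orthonormal device basis for a gaze direction: column 1 is the boresight
# unit vector, columns 2-3 span the microphone plane
device_basis <- function(az, el) {
  azr <- az * pi / 180
  elr <- el * pi / 180
  e1 <- c(cos(elr) * cos(azr), cos(elr) * sin(azr), sin(elr))
  e2 <- c(-sin(azr), cos(azr), 0)
  e3 <- c(e1[2] * e2[3] - e1[3] * e2[2],
          e1[3] * e2[1] - e1[1] * e2[3],
          e1[1] * e2[2] - e1[2] * e2[1])
  cbind(e1, e2, e3)
}

# per-reflector echo delay (samples, 0-based) and linear amplitude for one
# (pose, direction, mic); drops reflectors beyond the recording window
echo_components <- function(scene, pose, direction, mic_index, spec) {
  refl <- scene$reflectors
  if (nrow(refl) == 0)
    return(list(delay = integer(0), amp = numeric(0)))
  B <- device_basis(direction[1], direction[2])
  dvec <- sweep(as.matrix(refl[, c("x", "y", "z")]), 2, pose)
  r0 <- sqrt(rowSums(dvec^2))
  if (any(r0 == 0)) stop("degenerate geometry: pose coincides with a reflector")
  offset_deg <- acos(pmin(1, pmax(-1, dvec %*% B[, 1] / r0))) * 180 / pi
  gain <- beam_gain(offset_deg, spec$beam_ref_khz, spec)
  micpos <- pose + as.vector(B %*% spec$mic_offsets[, mic_index])
  rm <- sqrt(rowSums(sweep(as.matrix(refl[, c("x", "y", "z")]), 2, micpos)^2))
  if (any(rm == 0)) stop("degenerate geometry: microphone inside a reflector")
  delay <- as.integer(round((r0 + rm) / spec$c * spec$sample_rate))
  amp <- refl$strength * as.vector(gain) / (r0 * rm)
  keep <- delay < spec$n_samples
  list(delay = delay[keep], amp = amp[keep])
}

# saturated pickup of the emitted call at t = 0 (the emission overloads the
# microphones; templates blank this region anyway)
call_pickup <- function(spec, call = call_waveform(spec)) {
  pmin(1, pmax(-1, spec$saturation_gain * call))
}

# synthesize one waveform using the current RNG state (internal)
synth_wave <- function(comp, spec, call, pickup) {
  w <- add_echoes_cpp(spec$n_samples, c(pickup, rep(0, spec$n_samples - length(pickup))),
                      call, comp$delay, comp$amp)
  if (spec$self_noise_level > 0)
    w <- w + rnorm(spec$n_samples, 0, spec$self_noise_level)
  w
}

#' Synthesize one echo train
#'
#' Forward model for a single recording: the saturated call pickup at t = 0,
#' plus, for every reflector in range, a copy of the call delayed by the
#' two-way travel time and scaled by `strength * beam_gain / r^2` (spherical
#' spreading both ways; the beam gain is evaluated at the reference
#' frequency), plus white Gaussian device noise.
#'
#' @param scene a [generate_scene()] result.
#' @param pose device position, 3-vector, metres.
#' @param direction `c(az, el)` in degrees; must belong to `spec$grid`.
#' @param mic_index microphone index (1-based).
#' @param spec a [device_spec()].
#' @param rng_seed integer seed for the device noise.
#' @return an object of class `echo_train`: list with `waveform` (length
#'   `spec$n_samples`), `sample_rate`, and the identifying indices.
#' @export
synthesize_echo_train <- function(scene, pose, direction, mic_index, spec,
                                  rng_seed = 1) {
  dirs <- spec$grid$directions
  hit <- which(abs(dirs$az - direction[1]) < 1e-9 &
               abs(dirs$el - direction[2]) < 1e-9)
  if (length(hit) != 1) stop("direction does not belong to the device grid")
  call <- call_waveform(spec)
  comp <- echo_components(scene, pose, direction, mic_index, spec)
  w <- withr::with_seed(rng_seed,
                        synth_wave(comp, spec, call, call_pickup(spec, call)))
  structure(list(waveform = w, sample_rate = spec$sample_rate,
                 position_index = NA_integer_, direction_index = hit,
                 mic_index = mic_index, repeat_index = NA_integer_),
            class = "echo_train")
}

#' Synthesize a full ensonification dataset
#'
#' Produces exactly `positions x directions x repeats x mics` echo trains.
#' Repeats share the deterministic echo structure and differ only in the
#' device-noise realization. Waveforms are materialized in memory; for
#' full-device position runs prefer the streaming
#' [simulate_position_templates()].
#'
#' @param scene a `scene`.
#' @param design a `sampling_design`.
#' @param spec a [device_spec()].
#' @param rng_seed integer seed.
#' @return an object of class `echo_dataset`: list with `waves` (matrix,
#'   `n_samples` x N) and `meta` (data.frame with `position_index`,
#'   `direction_index`, `mic_index`, `repeat_index`), plus `spec`.
#' @export
generate_dataset <- function(scene, design, spec, rng_seed = 1) {
  dirs <- spec$grid$directions
  npos <- nrow(design$poses)
  nd <- nrow(dirs)
  N <- npos * nd * spec$n_repeats * spec$n_mics
  call <- call_waveform(spec)
  pickup <- call_pickup(spec, call)
  waves <- matrix(0, nrow = spec$n_samples, ncol = N)
  meta <- data.frame(position_index = integer(N), direction_index = integer(N),
                     mic_index = integer(N), repeat_index = integer(N))
  withr::with_seed(rng_seed, {
    col <- 0L
    for (p in seq_len(npos)) {
      pose <- design$poses[p, ]
      for (d in seq_len(nd)) {
        for (m in seq_len(spec$n_mics)) {
          comp <- echo_components(scene, pose, c(dirs$az[d], dirs$el[d]), m, spec)
          for (r in seq_len(spec$n_repeats)) {
            col <- col + 1L
            waves[, col] <- synth_wave(comp, spec, call, pickup)
            meta$position_index[col] <- p
            meta$direction_index[col] <- d
            meta$mic_index[col] <- m
            meta$repeat_index[col] <- r
          }
        }
      }
    }
  })
  structure(list(waves = waves, meta = meta, spec = spec),
            class = "echo_dataset")
}

#' @export
print.echo_dataset <- function(x, ...) {
  cat(sprintf("<echo_dataset> %d echo trains of %d samples\n",
              ncol(x$waves), nrow(x$waves)))
  invisible(x)
}
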