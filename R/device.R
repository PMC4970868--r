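#' Direction grid of the panoramic sampling device
#'
#' The ensonification device sweeps a pan-tilt grid of gaze directions. The
#' canonical grid covers azimuths -150..150 degrees in 10 degree steps (31
#' values) and elevations -25..39.8 degrees in 10.8 degree steps (7 values),
#' i.e. 217 directions. Smaller grids can be built for quick experiments.
#'
#' Directions are ordered elevation-major: all azimuths at the lowest
#' elevation first. `direction_index` is 1-based.
#'
#' @param azimuths numeric vector of azimuth angles, degrees.
#' @param elevations numeric vector of elevation angles, degrees.
#' @return an object of class `direction_grid` with elements `azimuths`,
#'   `elevations` and a data.frame `directions` with columns
#'   `direction_index`, `az_idx`, `el_idx`, `az`, `el`.
#' @export
direction_grid <- function(azimuths = seq(-150, 150, by = 10),
                           elevations = seq(-25, by = 10.8, length.out = 7)) {
  stopifnot(length(azimuths) >= 1, length(elevations) >= 1)
  d <- expand.grid(az_idx = seq_along(azimuths), el_idx = seq_along(elevations),
                   KEEP.OUT.ATTRS = FALSE)
  d <- d[order(d$el_idx, d$az_idx), , drop = FALSE]
  d$az <- azimuths[d$az_idx]
  d$el <- elevations[d$el_idx]
  d <- cbind(direction_index = seq_len(nrow(d)), d)
  rownames(d) <- NULL
  structure(list(azimuths = azimuths, elevations = elevations, directions = d),
            class = "direction_grid")
}

#' @export
print.direction_grid <- function(x, ...) {
  cat(sprintf("<direction_grid> %d az x %d el = %d directions\n",
              length(x$azimuths), length(x$elevations), nrow(x$directions)))
  invisible(x)
}

n_directions <- function(grid) nrow(grid$directions)

#' Microphone array layout
#'
#' Compact planar array in the device frame (boresight = +x): one centre
#' microphone plus two concentric rings in the y-z plane, all within a 5 cm
#' aperture. Inter-microphone differences are second order for the templates
#' (which average across microphones), so the exact layout is not critical.
#'
#' @param n_mics number of microphones.
#' @param radius outer ring radius in metres.
#' @return a 3 x n_mics matrix of offsets (metres) in the device frame.
#' @export
mic_array <- function(n_mics = 31, radius = 0.024) {
  stopifnot(n_mics >= 1)
  pts <- matrix(0, nrow = 3, ncol = n_mics)
  if (n_mics > 1) {
    n1 <- min(n_mics - 1, 10L)
    n2 <- n_mics - 1L - n1
    a1 <- 2 * pi * seq_len(n1) / max(n1, 1)
    pts[2, 1 + seq_len(n1)] <- radius / 2 * cos(a1)
    pts[3, 1 + seq_len(n1)] <- radius / 2 * sin(a1)
    if (n2 > 0) {
      a2 <- 2 * pi * seq_len(n2) / n2
      pts[2, 1 + n1 + seq_len(n2)] <- radius * cos(a2)
      pts[3, 1 + n1 + seq_len(n2)] <- radius * sin(a2)
    }
  }
  pts
}

#' Ensonification device specification
#'
#' Emulates a panoramic ensonification device: a 1 ms hyperbolic FM call
#' sweeping 100 to 40 kHz, 34 ms recordings at 219 kSamples/s, 31
#' microphones, a 31 x 7 azimuth-elevation grid, 3 repeats per direction and
#' a virtual emission beam with a 20 degree two-sided 3 dB opening angle at
#' 55 kHz.
#'
#' @param sample_rate samples per second.
#' @param record_duration recording window, seconds (from call onset).
#' @param call_f0,call_f1 sweep start/end frequencies, kHz.
#' @param call_duration call length, seconds.
#' @param n_mics number of microphones.
#' @param mic_offsets 3 x n_mics matrix of metre offsets in the device frame
#'   (boresight = +x); defaults to [mic_array()].
#' @param grid a [direction_grid()].
#' @param n_repeats measurements per direction.
#' @param beam_width_3db two-sided 3 dB beam opening angle, degrees, at
#'   `beam_ref_khz`.
#' @param beam_ref_khz reference frequency of the beam width, kHz.
#' @param self_noise_level standard deviation of the white Gaussian device
#'   noise, linear amplitude (full scale = 1). The device's internal noise
#'   guarantees a non-zero template noise floor even with no reflectors.
#' @param saturation_gain gain applied to the call pickup before clipping to
#'   full scale; models the emission saturating the microphones.
#' @param c speed of sound, m/s.
#' @return an object of class `device_spec`.
#' @export
device_spec <- function(sample_rate = 219000,
                        record_duration = 34e-3,
                        call_f0 = 100, call_f1 = 40,
                        call_duration = 1e-3,
                        n_mics = 31,
                        mic_offsets = mic_array(n_mics),
                        grid = direction_grid(),
                        n_repeats = 3,
                        beam_width_3db = 20,
                        beam_ref_khz = 55,
                        self_noise_level = 0.002,
                        saturation_gain = 20,
                        c = 343) {
  stopifnot(sample_rate > 0, record_duration > 0, call_duration > 0,
            call_f0 > call_f1, call_f1 > 0, n_mics >= 1, n_repeats >= 1,
            ncol(mic_offsets) == n_mics, nrow(mic_offsets) == 3,
            beam_width_3db > 0, self_noise_level >= 0, c > 0)
  n_samples <- round(record_duration * sample_rate)
  structure(list(sample_rate = sample_rate,
                 record_duration = record_duration,
                 n_samples = n_samples,
                 call_f0 = call_f0, call_f1 = call_f1,
                 call_duration = call_duration,
                 n_mics = n_mics, mic_offsets = mic_offsets,
                 grid = grid, n_repeats = n_repeats,
                 beam_width_3db = beam_width_3db,
                 beam_ref_khz = beam_ref_khz,
                 self_noise_level = self_noise_level,
                 saturation_gain = saturation_gain,
                 c = c),
            class = "device_spec")
}

#' @export
print.device_spec <- function(x, ...) {
  cat(sprintf(paste0("<device_spec> %g->%g kHz HFM %.1f ms | %.0f ms window @",
                     " %g kS/s (%d samples) | %d mics | %d directions x %d",
                     " repeats\n"),
              x$call_f0, x$call_f1, x$call_duration * 1e3,
              x$record_duration * 1e3, x$sample_rate / 1e3, x$n_samples,
              x$n_mics, n_directions(x$grid), x$n_repeats))
  invisible(x)
}

#' Maximum two-way sonar range of a device
#'
#' Reflectors farther than `record_duration * c / 2` cannot return an echo
#' inside the recording window.
#'
#' @param spec a [device_spec()].
#' @return range in metres.
#' @export
sonar_range <- function(spec) spec$record_duration * spec$c / 2

#' Sampling designs: isolated spots and straight transects
#'
#' `spots_design()` places the device at isolated, independent positions;
#' `transect_design()` places it along a straight line of evenly spaced
#' positions (spacing in metres) starting at `origin` and running along
#' `axis`.
#'
#' @param poses matrix with one row per pose and columns x, y, z (metres).
#' @param n_positions number of transect positions.
#' @param spacing transect spacing, metres.
#' @param origin 3-vector, start of the transect.
#' @param axis 3-vector, direction of the transect (normalised internally).
#' @return an object of class `sampling_design` with fields `poses`,
#'   `design_name`, `spacing`.
#' @export
spots_design <- function(poses) {
  poses <- as.matrix(poses)
  stopifnot(ncol(poses) == 3)
  structure(list(poses = poses, design_name = "spots", spacing = NA_real_),
            class = "sampling_design")
}

#' @rdname spots_design
#' @export
transect_design <- function(n_positions, spacing, origin = c(0, 0, 0),
                            axis = c(1, 0, 0)) {
  stopifnot(n_positions >= 2, spacing > 0)
  axis <- axis / sqrt(sum(axis^2))
  poses <- t(sapply(seq_len(n_positions) - 1,
                    function(k) origin + k * spacing * axis))
  structure(list(poses = poses, design_name = "transect", spacing = spacing),
            class = "sampling_design")
}

#' Echo-train count contracts for a design
#'
#' The number of echo trains a design produces is fixed by its geometry:
#' `positions x directions x repeats` per microphone, times the number of
#' microphones in total. These arithmetic contracts are what the simulated
#' datasets are checked against.
#'
#' @param design a `sampling_design`.
#' @param spec a [device_spec()].
#' @return a list with `per_mic`, `total` and `n_templates` counts.
#' @export
dataset_counts <- function(design, spec) {
  npos <- nrow(design$poses)
  nd <- n_directions(spec$grid)
  per_mic <- as.integer(npos * nd * spec$n_repeats)
  list(per_mic = per_mic,
       total = as.integer(per_mic * spec$n_mics),
       n_templates = as.integer(npos * nd))
}
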