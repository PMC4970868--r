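#' Auditory periphery parameters
#'
#' Gammatone filterbank with centre frequencies 30..100 kHz in 5 kHz steps
#' (15 channels), 4th-order all-pole gammatone channels with ERB-scaled
#' bandwidths (b = bw_factor * ERB(cf)), half-wave rectification, power-law
#' compression with exponent 0.4 and a second-order (12 dB/octave)
#' Butterworth low-pass at 1 kHz. Order, bandwidth scaling and cut-off are
#' exposed because the cited periphery family does not pin them down; the
#' defaults are the standard choices.
#'
#' @param sample_rate samples per second of the waveforms to be processed.
#' @param cf_khz centre frequencies, kHz.
#' @param order gammatone filter order.
#' @param bw_factor bandwidth scale relative to ERB (1.019 for order 4).
#' @param compress_exp compression exponent.
#' @param lp_cutoff low-pass cut-off, Hz.
#' @return a list of class `auditory_params` (includes the low-pass biquad
#'   coefficients).
#' @export
auditory_params <- function(sample_rate, cf_khz = seq(30, 100, by = 5),
                            order = 4, bw_factor = 1.019,
                            compress_exp = 0.4, lp_cutoff = 1000) {
  stopifnot(sample_rate > 0, lp_cutoff > 0, lp_cutoff < sample_rate / 2,
            all(cf_khz * 1000 < sample_rate / 2))
  bw <- signal::butter(2, lp_cutoff / (sample_rate / 2), type = "low")
  structure(list(sample_rate = sample_rate, cf_khz = cf_khz, order = order,
                 bw_factor = bw_factor, compress_exp = compress_exp,
                 lp_cutoff = lp_cutoff, lp_b = bw$b, lp_a = bw$a),
            class = "auditory_params")
}

#' Cochleogram of an echo train
#'
#' Runs the auditory periphery model on a waveform: per channel, gammatone
#' band-pass, half-wave rectification, compression (magnitude^0.4), 1 kHz
#' low-pass. Output length equals input length; the result is not dechirped.
#'
#' @param echo an `echo_train` or a numeric waveform.
#' @param params an [auditory_params()]; defaults to the model designed at
#'   the echo's sample rate.
#' @param sample_rate required when `echo` is a bare numeric vector.
#' @return an object of class `cochleogram`: list with `activations`
#'   (channels x time, non-negative), `center_frequencies` (kHz),
#'   `sample_rate`, `dechirped = FALSE`.
#' @export
cochleogram <- function(echo, params = NULL, sample_rate = NULL) {
  if (inherits(echo, "echo_train")) {
    wave <- echo$waveform
    fs <- echo$sample_rate
  } else {
    wave <- as.numeric(echo)
    fs <- sample_rate
    if (is.null(fs)) stop("sample_rate is required for a bare waveform")
  }
  if (is.null(params)) params <- auditory_params(fs)
  if (!isTRUE(all.equal(params$sample_rate, fs)))
    stop(sprintf("sample-rate mismatch: model designed at %g, echo at %g",
                 params$sample_rate, fs))
  act <- cochleogram_cpp(wave, fs, params$cf_khz * 1000, params$order,
                         params$bw_factor, params$compress_exp,
                         params$lp_b, params$lp_a)
  structure(list(activations = act, center_frequencies = params$cf_khz,
                 sample_rate = fs, dechirped = FALSE),
            class = "cochleogram")
}

#' @export
print.cochleogram <- function(x, ...) {
  cat(sprintf("<cochleogram> %d channels x %d samples (%sdechirped)\n",
              nrow(x$activations), ncol(x$activations),
              if (x$dechirped) "" else "not "))
  invisible(x)
}

#' Dechirp a cochleogram
#'
#' Shifts each frequency channel in time (zero-padding at the end) so that
#' the per-channel maximum activation - dominated by the pickup of the
#' emitted sweep - is aligned across channels. The alignment target is the
#' earliest channel argmax, so all shifts are non-negative. Argmax ties are
#' broken to the earliest index. All-zero channels are left unshifted with a
#' warning.
#'
#' @param cg a non-dechirped `cochleogram`.
#' @return the dechirped `cochleogram` (same dimensions); per-channel
#'   argmaxes are all equal afterwards.
#' @export
dechirp <- function(cg) {
  stopifnot(inherits(cg, "cochleogram"))
  if (cg$dechirped) stop("cochleogram is already dechirped")
  act <- cg$activations
  n <- ncol(act)
  amax <- apply(act, 1, function(ch) if (all(ch == 0)) NA_integer_ else which.max(ch))
  if (anyNA(amax)) warning("silent (all-zero) channel left unshifted")
  if (all(is.na(amax))) {
    cg$dechirped <- TRUE
    return(cg)
  }
  target <- min(amax, na.rm = TRUE)
  for (ch in seq_len(nrow(act))) {
    if (is.na(amax[ch])) next
    s <- amax[ch] - target
    if (s > 0) act[ch, ] <- c(act[ch, (s + 1):n], rep(0, s))
  }
  cg$activations <- act
  cg$dechirped <- TRUE
  cg
}
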