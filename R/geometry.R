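#' Thickness of the echo integration shell
#'
#' Echoes arriving within one temporal integration interval tau are fused,
#' so the sonar integrates over a radial shell of thickness c * tau / 2
#' (two-way travel). 200 us at 343 m/s gives about 0.034 m.
#'
#' @param tau temporal integration interval, seconds.
#' @param c speed of sound, m/s.
#' @return shell thickness, metres.
#' @export
shell_thickness <- function(tau = 200e-6, c = 343) {
  stopifnot(tau >= 0, c > 0)
  c * tau / 2
}

#' Volume of space integrated into one echo sample
#'
#' The integration volume is approximated as a section of a spherical shell:
#' the opening angle of the section is the (full) beam width, the shell
#' thickness follows from the temporal integration. With solid angle
#' Omega = 2*pi*(1 - cos(beam_width/2)),
#' V = (Omega / 3) * ((r + delta_r)^3 - r^3).
#' The volume grows rapidly with distance: at 7.8 m a 45 degree beam already
#' integrates echoes from about 1 m^3, a 60 degree beam from about 2 m^3.
#'
#' @param r distance from the sonar, metres.
#' @param beam_width full opening angle of the beam, degrees (0 < bw < 360).
#' @param tau temporal integration interval, seconds.
#' @param c speed of sound, m/s.
#' @return volume, cubic metres.
#' @export
integration_volume <- function(r, beam_width, tau = 200e-6, c = 343) {
  stopifnot(r >= 0, beam_width > 0, beam_width < 360)
  delta_r <- shell_thickness(tau, c)
  omega <- 2 * pi * (1 - cos(beam_width / 2 * pi / 180))
  omega / 3 * ((r + delta_r)^3 - r^3)
}
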