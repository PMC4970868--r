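#' Generate a parametric acoustic scene
#'
#' Scenes are collections of ideal point reflectors. Three habitat archetypes
#' are supported: `"open"` (no reflector within sonar range of any pose),
#' `"semi-cluttered"` and `"cluttered"` (homogeneous Poisson point process at
#' the requested density inside `region`). Extended objects (boulders,
#' foliage) are built from seeded clusters of points by the corridor scene
#' constructors.
#'
#' @param archetype `"open"`, `"semi-cluttered"` or `"cluttered"`.
#' @param density reflectors per cubic metre (ignored for `"open"`).
#' @param region list with `xlim`, `ylim`, `zlim` (each a length-2 numeric),
#'   the bounding box of the reflector field, metres.
#' @param rng_seed integer seed; identical arguments and seed give an
#'   identical scene.
#' @param strength_meanlog,strength_sdlog log-normal parameters for reflector
#'   strengths (linear reflectivity at 1 m).
#' @return an object of class `scene`: a list with `reflectors` (data.frame
#'   x, y, z, strength, kind), `archetype`, `rng_seed`.
#' @export
generate_scene <- function(archetype, density = 0,
                           region = list(xlim = c(-6, 6), ylim = c(-6, 6),
                                         zlim = c(-3, 3)),
                           rng_seed = 1,
                           strength_meanlog = log(0.8),
                           strength_sdlog = 0.4) {
  archetype <- match.arg(archetype, c("open", "semi-cluttered", "cluttered"))
  stopifnot(density >= 0)
  vol <- diff(region$xlim) * diff(region$ylim) * diff(region$zlim)
  if (vol <= 0) stop("degenerate region: zero volume")
  refl <- withr::with_seed(rng_seed, {
    if (archetype == "open") {
      data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
                 strength = numeric(0), kind = character(0))
    } else {
      n <- rpois(1, density * vol)
      data.frame(x = runif(n, region$xlim[1], region$xlim[2]),
                 y = runif(n, region$ylim[1], region$ylim[2]),
                 z = runif(n, region$zlim[1], region$zlim[2]),
                 strength = rlnorm(n, strength_meanlog, strength_sdlog),
                 kind = rep("point-scatterer", n))
    }
  })
  structure(list(reflectors = refl, archetype = archetype,
                 rng_seed = rng_seed),
            class = "scene")
}

#' @export
print.scene <- function(x, ...) {
  cat(sprintf("<scene> archetype=%s, %d reflectors (seed %d)\n",
              x$archetype, nrow(x$reflectors), x$rng_seed))
  invisible(x)
}

cluster_points <- function(centre, n, sd, strength, kind) {
  data.frame(x = rnorm(n, centre[1], sd),
             y = rnorm(n, centre[2], sd),
             z = rnorm(n, centre[3], sd),
             strength = rep(strength, n),
             kind = rep(kind, n))
}

#' Corridor scenes: strong distant reflectors vs weak near reflectors
#'
#' Two contrasting corridor habitats flanking a straight transect running
#' along +x from the origin. `boulder_corridor()` lines the corridor with a
#' few strong, compact rock clusters at `wall_distance` (default 3 m) from
#' the transect line: strong echoes from distant reflectors with slow
#' acoustic motion parallax. `vegetation_corridor()` lines it with many weak
#' foliage scatterers close to the line (0.8-1.8 m): weak echoes from near
#' reflectors with fast parallax.
#'
#' @param length_m corridor (transect) length, metres; reflectors extend 3 m
#'   beyond each end.
#' @param rng_seed integer seed.
#' @param wall_distance lateral distance of the boulder walls, metres.
#' @param n_boulders_per_side number of boulders per side.
#' @param boulder_strength per-point reflectivity of boulder scatterers.
#' @param foliage_per_metre foliage scatterers per metre of corridor per side.
#' @param foliage_strength per-point reflectivity of foliage scatterers.
#' @return a `scene`.
#' @export
boulder_corridor <- function(length_m = 10, rng_seed = 1, wall_distance = 3,
                             n_boulders_per_side = max(8, round(1.5 * length_m)),
                             boulder_strength = 3) {
  refl <- withr::with_seed(rng_seed, {
    out <- list()
    for (side in c(-1, 1)) {
      # roughly evenly spaced boulders with jitter: a lined corridor wall
      cx <- seq(-3, length_m + 3, length.out = n_boulders_per_side) +
        runif(n_boulders_per_side, -0.8, 0.8)
      for (i in seq_len(n_boulders_per_side)) {
        ctr <- c(cx[i], side * wall_distance * runif(1, 0.9, 1.1),
                 runif(1, -0.5, 1))
        out[[length(out) + 1]] <-
          cluster_points(ctr, n = 12, sd = 0.3,
                         strength = boulder_strength, kind = "boulder")
      }
    }
    do.call(rbind, out)
  })
  structure(list(reflectors = refl, archetype = "boulder-corridor",
                 rng_seed = rng_seed),
            class = "scene")
}

#' @rdname boulder_corridor
#' @export
vegetation_corridor <- function(length_m = 10, rng_seed = 1,
                                foliage_per_metre = 40,
                                foliage_strength = 0.5) {
  refl <- withr::with_seed(rng_seed, {
    out <- list()
    for (side in c(-1, 1)) {
      n <- rpois(1, foliage_per_metre * (length_m + 6))
      out[[length(out) + 1]] <-
        data.frame(x = runif(n, -3, length_m + 3),
                   y = side * runif(n, 0.8, 1.8),
                   z = runif(n, -1, 2),
                   strength = rlnorm(n, log(foliage_strength), 0.4),
                   kind = rep("foliage-element", n))
    }
    do.call(rbind, out)
  })
  structure(list(reflectors = refl, archetype = "vegetation-corridor",
                 rng_seed = rng_seed),
            class = "scene")
}

#' Virtual emission beam gain
#'
#' Gaussian-tapered beam with a two-sided 3 dB opening angle of
#' `spec$beam_width_3db` degrees at the reference frequency, scaling
#' inversely with frequency (constant-aperture behaviour). The gain is 1 on
#' boresight and strictly decreasing in |offset|.
#'
#' @param direction_offset angle from boresight, degrees.
#' @param frequency frequency, kHz; must lie within the call sweep.
#' @param spec a [device_spec()].
#' @return linear amplitude gain in (0, 1].
#' @export
beam_gain <- function(direction_offset, frequency, spec) {
  if (any(frequency < spec$call_f1 | frequency > spec$call_f0))
    stop("frequency outside the call sweep")
  half_width <- (spec$beam_width_3db / 2) * (spec$beam_ref_khz / frequency)
  10^(-(3 / 20) * (direction_offset / half_width)^2)
}
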