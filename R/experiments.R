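#' Noise-floor estimation from reflector-free runs
#'
#' Emulates pointing the device at empty space: several full panoramic runs
#' with no reflector in range, processed by the complete template pipeline;
#' the floor is the maximum template value observed.
#'
#' @param spec a [device_spec()].
#' @param n_runs number of reflector-free panoramic runs.
#' @param rng_seed integer seed.
#' @return `n_f`.
#' @export
noise_floor_from_device <- function(spec, n_runs = 3, rng_seed = 1) {
  empty <- generate_scene("open", rng_seed = rng_seed)
  sets <- lapply(seq_len(n_runs), function(k) {
    simulate_position_templates(empty, c(0, 0, 0), spec,
                                rng_seed = rng_seed * 100L + k)
  })
  estimate_noise_floor(sets)
}

# smallest 3x3 sub-grid of `grid` centred on the grid direction nearest
# (0 az, 0 el); used to build single-echo calibration templates with the
# same neighbourhood averaging as the full pipeline
calibration_patch_grid <- function(grid) {
  axis_patch <- function(values) {
    i <- which.min(abs(values))
    if (length(values) >= 3) i <- min(max(i, 2L), length(values) - 1L)
    values[max(1, i - 1):min(length(values), i + 1)]
  }
  az <- axis_patch(grid$azimuths)
  el <- axis_patch(grid$elevations)
  list(grid = direction_grid(az, el),
       centre = c(az[which.min(abs(az))], el[which.min(abs(el))]))
}

#' Template of a single synthetic echo
#'
#' Builds the place template of one noiseless recording containing a single
#' boresight point reflector at `range_m`, processed by the full pipeline
#' (including the 3x3 neighbourhood averaging, evaluated on the minimal
#' patch around the gaze direction nearest straight ahead). `scale_db`
#' scales the echo waveform amplitude; the 2 dB sibling used for noise
#' calibration is obtained with `scale_db = 2`.
#'
#' @param spec a [device_spec()].
#' @param range_m reflector range, metres.
#' @param scale_db echo amplitude scaling, dB.
#' @param strength reflector strength at 0 dB.
#' @return numeric template vector (centre direction of the patch).
#' @export
single_echo_template <- function(spec, range_m = 2, scale_db = 0,
                                 strength = 1) {
  patch <- calibration_patch_grid(spec$grid)
  pspec <- spec
  pspec$grid <- patch$grid
  pspec$self_noise_level <- 0
  u <- device_basis(patch$centre[1], patch$centre[2])[, 1]
  pos <- range_m * u
  scn <- structure(list(reflectors = data.frame(x = pos[1], y = pos[2],
                                                z = pos[3],
                                                strength = strength *
                                                  10^(scale_db / 20),
                                                kind = "point-scatterer"),
                        archetype = "calibration", rng_seed = 0L),
                   class = "scene")
  set <- simulate_position_templates(scn, c(0, 0, 0), pspec, rng_seed = 1)
  centre_row <- which(set$meta$az == patch$centre[1] &
                      set$meta$el == patch$centre[2])
  as.numeric(set$values[centre_row, ])
}

#' Calibrate the full noise model for a device
#'
#' Estimates the noise floor from reflector-free runs, builds the single-echo
#' calibration pair (reference and `jnd_db`-louder sibling), floors both at
#' `n_f`, and solves for the Gaussian noise variance that discriminates the
#' pair at the `criterion` correct rate.
#'
#' @param spec a [device_spec()].
#' @param jnd_db just-noticeable echo intensity difference, dB.
#' @param criterion two-alternative correct rate at the JND.
#' @param range_m calibration reflector range, metres.
#' @param n_floor_runs reflector-free panoramic runs for the floor.
#' @param rng_seed integer seed.
#' @param floor_templates floor the calibration pair at `n_f` before solving
#'   (the stored-template convention used throughout).
#' @return a [noise_model()]; the calibration pair and closed-form details
#'   are attached as attribute `calibration`.
#' @export
calibrate_noise_model <- function(spec, jnd_db = 2, criterion = 0.75,
                                  range_m = 2, n_floor_runs = 3, rng_seed = 1,
                                  floor_templates = TRUE) {
  n_f <- noise_floor_from_device(spec, n_floor_runs, rng_seed)
  t_ref <- single_echo_template(spec, range_m, scale_db = 0)
  t_jnd <- single_echo_template(spec, range_m, scale_db = jnd_db)
  if (floor_templates) {
    t_ref <- apply_floor(t_ref, n_f)
    t_jnd <- apply_floor(t_jnd, n_f)
  }
  cal <- calibrate_sigma(t_ref, t_jnd, criterion)
  nm <- noise_model(n_f, cal$sigma_n2, jnd_db, criterion)
  attr(nm, "calibration") <- c(cal, list(t_ref = t_ref, t_jnd = t_jnd,
                                         range_m = range_m))
  nm
}

#' Study configurations: isolated spots across clutter levels
#'
#' Twelve independent positions - four open, four semi-cluttered, four
#' cluttered - each a fresh Poisson scene around the device, mirroring a
#' park survey across clutter levels. `scale = "full"` uses the canonical
#' device (31 microphones, 31 x 7 grid); `scale = "scaled"` keeps the full
#' 217-direction grid but 2 microphones, for quick runs (microphone count
#' only affects averaging depth).
#'
#' @param scale `"scaled"` or `"full"`.
#' @param rng_seed integer seed from which scene seeds are derived.
#' @param density_semi,density_cluttered reflector densities, per m^3.
#' @return a config list consumed by [run_spots_experiment()].
#' @export
spots_study_config <- function(scale = c("scaled", "full"), rng_seed = 1,
                               density_semi = 0.05, density_cluttered = 0.4) {
  scale <- match.arg(scale)
  spec <- if (scale == "full") device_spec()
          else device_spec(n_mics = 2, mic_offsets = mic_array(2))
  archetypes <- rep(c("open", "semi-cluttered", "cluttered"), each = 4)
  density <- c(open = 0, `semi-cluttered` = density_semi,
               cluttered = density_cluttered)
  scenes <- lapply(seq_along(archetypes), function(p) {
    generate_scene(archetypes[p], density[[archetypes[p]]],
                   rng_seed = (rng_seed %% 1000003L) * 100L + p)
  })
  list(spec = spec, scenes = scenes,
       design = spots_design(matrix(0, nrow = 12, ncol = 3)),
       habitat = archetypes, rng_seed = rng_seed, scale = scale)
}

#' Run the spots experiment end to end
#'
#' Simulates all twelve positions, calibrates the noise model (floor +
#' Gaussian variance), floors the templates, classifies every template
#' within its position's panorama, and computes angular catchment profiles.
#'
#' @param config from [spots_study_config()].
#' @param noise optional pre-calibrated [noise_model()].
#' @return list with `templates` (floored), `noise`, `classification` (with
#'   a `habitat` column), `angular` (see [angular_catchment()]),
#'   `habitat_summary` and `counts`.
#' @export
run_spots_experiment <- function(config, noise = NULL) {
  templates <- simulate_design_templates(config$scenes, config$design,
                                         config$spec,
                                         rng_seed = config$rng_seed)
  if (is.null(noise))
    noise <- calibrate_noise_model(config$spec,
                                   rng_seed = config$rng_seed + 7)
  templates <- apply_floor(templates, noise$n_f)
  cls <- classify_set(templates, noise, rng_seed = config$rng_seed + 11)
  cls$habitat <- config$habitat[cls$position_index]
  ang <- angular_catchment(templates, noise$sigma_n2)
  ang$catchment$habitat <- config$habitat[ang$catchment$position_index]
  hs <- do.call(rbind, lapply(split(cls, cls$habitat), function(d) {
    data.frame(habitat = d$habitat[1], mean_pc = mean(d$pc),
               median_pc = median(d$pc),
               median_angular_error = median(d$angular_error))
  }))
  rownames(hs) <- NULL
  list(templates = templates, noise = noise, classification = cls,
       angular = ang, habitat_summary = hs,
       counts = dataset_counts(config$design, config$spec))
}

#' Study configurations: corridor transects
#'
#' A straight transect through one of two contrasting corridors: `"boulders"`
#' (few strong rock clusters 4 m from the line - strong distant reflectors,
#' the layout of a boulder-lined commuting corridor) or `"vegetation"`
#' (dense weak foliage 0.8-1.8 m from the line - weak near reflectors).
#' `scale = "full"` uses the canonical device and the surveyed designs (50
#' positions at 20 cm for the boulder corridor, 40 at 25 cm for the
#' vegetation corridor); `scale = "scaled"` uses 14 positions at 25 cm, a
#' 21-azimuth single-elevation grid and 2 microphones.
#'
#' @param kind `"boulders"` or `"vegetation"`.
#' @param scale `"scaled"` or `"full"`.
#' @param rng_seed integer seed (drives the scene draw).
#' @return a config list consumed by [run_transect_experiment()].
#' @export
transect_study_config <- function(kind = c("boulders", "vegetation"),
                                  scale = c("scaled", "full"), rng_seed = 1) {
  kind <- match.arg(kind)
  scale <- match.arg(scale)
  if (scale == "full") {
    spec <- device_spec()
    design <- if (kind == "boulders") transect_design(50, 0.20)
              else transect_design(40, 0.25)
  } else {
    # the 10 degree azimuth step is kept: with the neighbourhood averaging it
    # sets how confusable adjacent gaze directions are, which drives the
    # classification/continuity trade-off; the 25 cm spacing keeps per-step
    # parallax of the distant wall below the beam width
    spec <- device_spec(n_mics = 2, mic_offsets = mic_array(2),
                        grid = direction_grid(seq(-90, 90, by = 10),
                                              c(-14.2, -3.4, 7.4)))
    design <- transect_design(12, 0.25)
  }
  length_m <- (nrow(design$poses) - 1) * design$spacing
  scene <- if (kind == "boulders") boulder_corridor(length_m, rng_seed)
           else vegetation_corridor(length_m, rng_seed)
  list(spec = spec, scene = scene, design = design, kind = kind,
       rng_seed = rng_seed, scale = scale)
}

#' Run a transect experiment end to end
#'
#' Simulates templates along the transect, floors them, classifies each
#' within its position's panorama, and computes linear catchment distances
#' and their per-direction medians.
#'
#' @param config from [transect_study_config()].
#' @param noise optional pre-calibrated [noise_model()] (calibrated from the
#'   config's device when omitted).
#' @return list with `templates`, `noise`, `classification`, `linear` (see
#'   [linear_catchment()]), `merged` (per-template pc + catchment) and
#'   `counts`.
#' @export
run_transect_experiment <- function(config, noise = NULL) {
  templates <- simulate_design_templates(config$scene, config$design,
                                         config$spec,
                                         rng_seed = config$rng_seed)
  if (is.null(noise))
    noise <- calibrate_noise_model(config$spec,
                                   rng_seed = config$rng_seed + 7)
  templates <- apply_floor(templates, noise$n_f)
  cls <- classify_set(templates, noise, rng_seed = config$rng_seed + 11)
  lin <- linear_catchment(templates, noise$sigma_n2)
  merged <- merge(cls, lin$per_template,
                  by = c("position_index", "direction_index"))
  merged$site <- config$kind
  list(templates = templates, noise = noise, classification = cls,
       linear = lin, merged = merged,
       counts = dataset_counts(config$design, config$spec))
}

#' Matched-seed contrast of the two corridor types
#'
#' Runs the boulder and vegetation corridors with a shared seed and noise
#' model and summarises the classification/continuity trade-off: median
#' linear catchment and mean P_c per corridor, plus the pooled rank
#' correlation and rank-sum comparisons.
#'
#' @param rng_seed integer seed shared by the pair.
#' @param scale passed to [transect_study_config()].
#' @param noise optional shared [noise_model()].
#' @return list with `boulders`, `vegetation` (experiment results),
#'   `median_catchment`, `mean_pc` (named 2-vectors) and `tradeoff`
#'   (see [tradeoff_report()]).
#' @export
corridor_contrast <- function(rng_seed = 1, scale = "scaled", noise = NULL) {
  cfg_b <- transect_study_config("boulders", scale, rng_seed)
  cfg_v <- transect_study_config("vegetation", scale, rng_seed)
  if (is.null(noise))
    noise <- calibrate_noise_model(cfg_b$spec, rng_seed = rng_seed + 7)
  res_b <- run_transect_experiment(cfg_b, noise)
  res_v <- run_transect_experiment(cfg_v, noise)
  pooled <- rbind(res_b$merged, res_v$merged)
  list(boulders = res_b, vegetation = res_v,
       median_catchment = c(boulders = median(res_b$merged$catchment_m),
                            vegetation = median(res_v$merged$catchment_m)),
       mean_pc = c(boulders = mean(res_b$merged$pc),
                   vegetation = mean(res_v$merged$pc)),
       tradeoff = tradeoff_report(pooled))
}
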