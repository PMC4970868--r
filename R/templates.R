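#' Blank the onset of a dechirped cochleogram
#'
#' Sets every sample earlier than `blank_duration` (default 5.8 ms,
#' corresponding to about 1 m of two-way travel) to zero in every channel, so
#' the saturated pickup of the emission and its decay never enter the
#' templates.
#'
#' @param cg a dechirped `cochleogram`.
#' @param blank_duration seconds; must be smaller than the record duration.
#' @return the blanked `cochleogram`.
#' @export
blank_onset <- function(cg, blank_duration = 5.8e-3) {
  stopifnot(inherits(cg, "cochleogram"))
  if (!cg$dechirped) stop("blank_onset expects a dechirped cochleogram")
  n <- ncol(cg$activations)
  if (blank_duration >= n / cg$sample_rate)
    stop("blank_duration must be smaller than the record duration")
  ns <- blank_samples(blank_duration, cg$sample_rate)
  if (ns > 0) cg$activations[, seq_len(ns)] <- 0
  cg
}

# number of leading samples with time < blank_duration (sample k is at
# (k-1)/fs); 5.8 ms at 219 kS/s -> 1271 samples (1270.2 rounded outward)
blank_samples <- function(blank_duration, sample_rate) {
  as.integer(ceiling(blank_duration * sample_rate - 1e-9))
}

#' Collapse cochleograms across frequency channels and microphones
#'
#' For each (direction, repeat) cell, the unweighted mean over all frequency
#' channels and all microphones gives one raw time profile; a complete
#' position yields `directions x repeats` profiles (651 for the canonical
#' device).
#'
#' @param cgs list of blanked, dechirped `cochleogram`s, all the same length.
#' @param meta data.frame with one row per element of `cgs`: columns
#'   `direction_index`, `mic_index`, `repeat_index`.
#' @param spec a [device_spec()] (defines the complete cell set).
#' @return list with `profiles` (matrix, one row per (direction, repeat)) and
#'   `meta` (data.frame `direction_index`, `repeat_index`).
#' @export
collapse <- function(cgs, meta, spec) {
  nd <- n_directions(spec$grid)
  stopifnot(length(cgs) == nrow(meta))
  key <- paste(meta$direction_index, meta$mic_index, meta$repeat_index)
  want <- expand.grid(direction_index = seq_len(nd),
                      mic_index = seq_len(spec$n_mics),
                      repeat_index = seq_len(spec$n_repeats))
  wkey <- paste(want$direction_index, want$mic_index, want$repeat_index)
  miss <- setdiff(wkey, key)
  if (length(miss) > 0)
    stop("incomplete position data, missing (direction mic repeat) cell: ",
         miss[1])
  n <- ncol(cgs[[1]]$activations)
  out_meta <- expand.grid(repeat_index = seq_len(spec$n_repeats),
                          direction_index = seq_len(nd))[, 2:1]
  profiles <- matrix(0, nrow = nrow(out_meta), ncol = n)
  for (i in seq_len(nrow(out_meta))) {
    sel <- which(meta$direction_index == out_meta$direction_index[i] &
                 meta$repeat_index == out_meta$repeat_index[i])
    acc <- rep(0, n)
    for (j in sel) acc <- acc + colMeans(cgs[[j]]$activations)
    profiles[i, ] <- acc / length(sel)
  }
  list(profiles = profiles, meta = out_meta)
}

# 3x3 grid neighbourhood members (azimuth index +-1, elevation index +-1,
# truncated at the grid edges; the azimuth range does not wrap)
grid_neighbours <- function(grid) {
  d <- grid$directions
  lapply(seq_len(nrow(d)), function(i) {
    which(abs(d$az_idx - d$az_idx[i]) <= 1 & abs(d$el_idx - d$el_idx[i]) <= 1)
  })
}

#' Average profiles across 3x3 neighbouring directions
#'
#' Replaces each direction's profile by the mean over its 3x3 grid
#' neighbourhood (azimuth index +-1, elevation index +-1), truncated at grid
#' edges; this widens the narrow emitter beam to a batlike virtual beam.
#' Repeats are processed independently.
#'
#' @param profiles matrix, one row per (direction, repeat).
#' @param meta data.frame `direction_index`, `repeat_index` matching rows.
#' @param grid the [direction_grid()].
#' @return matrix of the same shape and row order.
#' @export
spatial_average <- function(profiles, meta, grid) {
  nb <- grid_neighbours(grid)
  out <- profiles
  for (r in unique(meta$repeat_index)) {
    rows <- which(meta$repeat_index == r)
    row_of_dir <- integer(n_directions(grid))
    row_of_dir[meta$direction_index[rows]] <- rows
    for (i in rows) {
      members <- row_of_dir[nb[[meta$direction_index[i]]]]
      out[i, ] <- colMeans(profiles[members, , drop = FALSE])
    }
  }
  out
}

#' Downsample a profile by temporal integration
#'
#' Replaces the full-rate profile by the mean over consecutive bins of
#' `interval` seconds (350 us by default, the model's temporal integration
#' interval); a trailing partial bin is discarded. A 34 ms profile becomes a
#' 97-sample template.
#'
#' @param profiles numeric vector or matrix (rows are profiles) at
#'   `sample_rate`.
#' @param sample_rate samples per second.
#' @param interval integration interval, seconds.
#' @return vector/matrix of bin means, `floor(duration / interval)` long.
#' @export
downsample_profile <- function(profiles, sample_rate, interval = 350e-6) {
  vec <- is.null(dim(profiles))
  if (vec) profiles <- matrix(profiles, nrow = 1)
  n <- ncol(profiles)
  t <- (seq_len(n) - 1) / sample_rate
  bin <- floor(t / interval) + 1
  nbins <- floor(n / (interval * sample_rate))
  keep <- bin <= nbins
  g <- bin[keep]
  sums <- rowsum(t(profiles[, keep, drop = FALSE]), g)
  out <- t(sums / as.vector(table(g)))
  dimnames(out) <- NULL
  if (vec) as.numeric(out) else out
}

new_template_set <- function(values, meta, grid, sample_interval = 350e-6,
                             design_name = "spots", spacing = NA_real_) {
  stopifnot(nrow(values) == nrow(meta))
  structure(list(values = values, meta = meta, grid = grid,
                 sample_interval = sample_interval,
                 design_name = design_name, spacing = spacing),
            class = "template_set")
}

#' @export
print.template_set <- function(x, ...) {
  cat(sprintf("<template_set> %d templates of length %d (%d positions x %d directions)\n",
              nrow(x$values), ncol(x$values),
              length(unique(x$meta$position_index)),
              n_directions(x$grid)))
  invisible(x)
}

#' Number of templates in a set
#' @param set a `template_set`.
#' @return integer count.
#' @export
n_templates <- function(set) nrow(set$values)

#' Combine template sets
#'
#' Row-binds template sets that share a grid and sample interval;
#' `position_index` values must not collide unless `renumber = TRUE`.
#'
#' @param ... `template_set` objects.
#' @param renumber make position indices consecutive across sets.
#' @return a `template_set`.
#' @export
combine_template_sets <- function(..., renumber = TRUE) {
  sets <- list(...)
  stopifnot(length(sets) >= 1)
  offset <- 0L
  metas <- list()
  for (i in seq_along(sets)) {
    m <- sets[[i]]$meta
    if (renumber) {
      m$position_index <- m$position_index + offset
      offset <- max(m$position_index)
    }
    metas[[i]] <- m
  }
  meta <- do.call(rbind, metas)
  if (anyDuplicated(meta[, c("position_index", "direction_index")]))
    stop("duplicate (position_index, direction_index) pairs")
  new_template_set(do.call(rbind, lapply(sets, function(s) s$values)),
                   meta, sets[[1]]$grid, sets[[1]]$sample_interval,
                   design_name = sets[[1]]$design_name,
                   spacing = sets[[1]]$spacing)
}

# per-echo fused path: cochleogram -> dechirp -> blank -> channel mean
wave_profile <- function(wave, spec, params, blank_duration = 5.8e-3) {
  echo_profile_cpp(wave, spec$sample_rate, params$cf_khz * 1000, params$order,
                   params$bw_factor, params$compress_exp, params$lp_b,
                   params$lp_a, blank_samples(blank_duration, spec$sample_rate))
}

# shared tail of the template pipeline: (direction, repeat) profiles ->
# spatial average -> temporal integration -> repeat mean
profiles_to_templates <- function(profiles, meta, spec,
                                  sample_interval = 350e-6) {
  profiles <- spatial_average(profiles, meta, spec$grid)
  binned <- downsample_profile(profiles, spec$sample_rate, sample_interval)
  nd <- n_directions(spec$grid)
  values <- matrix(0, nrow = nd, ncol = ncol(binned))
  for (d in seq_len(nd)) {
    rows <- which(meta$direction_index == d)
    values[d, ] <- colMeans(binned[rows, , drop = FALSE])
  }
  values
}

#' Build place templates from a materialized echo dataset
#'
#' The full template pipeline: auditory periphery (cochleogram), dechirping,
#' onset blanking, averaging across frequency channels and microphones
#' (giving `directions x repeats` raw profiles per position), averaging
#' across 3x3 neighbouring directions, temporal integration at 350 us, and
#' averaging across repeats - one template per direction per position.
#'
#' @param dataset an [generate_dataset()] result.
#' @param blank_duration onset blank, seconds.
#' @param sample_interval temporal integration interval, seconds.
#' @param params [auditory_params()]; defaults to the dataset's sample rate.
#' @return a `template_set` with one row per (position, direction).
#' @export
build_templates <- function(dataset, blank_duration = 5.8e-3,
                            sample_interval = 350e-6, params = NULL) {
  spec <- dataset$spec
  if (is.null(params)) params <- auditory_params(spec$sample_rate)
  nd <- n_directions(spec$grid)
  positions <- sort(unique(dataset$meta$position_index))
  values <- list()
  metas <- list()
  pm <- expand.grid(repeat_index = seq_len(spec$n_repeats),
                    direction_index = seq_len(nd))[, 2:1]
  for (p in positions) {
    cols <- which(dataset$meta$position_index == p)
    sub <- dataset$meta[cols, ]
    profiles <- matrix(0, nrow = nrow(pm), ncol = spec$n_samples)
    counts <- integer(nrow(pm))
    row_of <- matrix(0L, nrow = nd, ncol = spec$n_repeats)
    row_of[cbind(pm$direction_index, pm$repeat_index)] <- seq_len(nrow(pm))
    for (k in seq_along(cols)) {
      i <- row_of[sub$direction_index[k], sub$repeat_index[k]]
      profiles[i, ] <- profiles[i, ] +
        wave_profile(dataset$waves[, cols[k]], spec, params, blank_duration)
      counts[i] <- counts[i] + 1L
    }
    if (any(counts != spec$n_mics))
      stop("incomplete position data for position ", p)
    profiles <- profiles / spec$n_mics
    values[[length(values) + 1]] <-
      profiles_to_templates(profiles, pm, spec, sample_interval)
    g <- spec$grid$directions
    metas[[length(metas) + 1]] <-
      data.frame(position_index = p, direction_index = g$direction_index,
                 az = g$az, el = g$el)
  }
  new_template_set(do.call(rbind, values), do.call(rbind, metas), spec$grid,
                   sample_interval)
}

#' Simulate and build the templates of one position (streaming)
#'
#' Runs synthesis and the full template pipeline for a single device
#' position without materializing the echo trains (one waveform lives in
#' memory at a time), so a full-device position (20,181 echo trains for the
#' canonical 217 x 31 x 3 design) runs in bounded memory. Stage counts are
#' attached as attribute `counts` (`n_echo_trains`, `n_profiles`,
#' `n_templates`).
#'
#' @param scene a `scene`.
#' @param pose device position, 3-vector, metres.
#' @param spec a [device_spec()].
#' @param rng_seed integer seed for the device noise.
#' @param position_index index recorded in the output meta.
#' @param blank_duration,sample_interval,params as in [build_templates()].
#' @return a single-position `template_set` (one template per direction).
#' @export
simulate_position_templates <- function(scene, pose, spec, rng_seed = 1,
                                        position_index = 1L,
                                        blank_duration = 5.8e-3,
                                        sample_interval = 350e-6,
                                        params = NULL) {
  if (is.null(params)) params <- auditory_params(spec$sample_rate)
  nd <- n_directions(spec$grid)
  dirs <- spec$grid$directions
  call <- call_waveform(spec)
  pickup <- call_pickup(spec, call)
  pm <- expand.grid(repeat_index = seq_len(spec$n_repeats),
                    direction_index = seq_len(nd))[, 2:1]
  profiles <- matrix(0, nrow = nrow(pm), ncol = spec$n_samples)
  row_of <- matrix(0L, nrow = nd, ncol = spec$n_repeats)
  row_of[cbind(pm$direction_index, pm$repeat_index)] <- seq_len(nrow(pm))
  n_trains <- 0L
  withr::with_seed(rng_seed, {
    for (d in seq_len(nd)) {
      for (m in seq_len(spec$n_mics)) {
        comp <- echo_components(scene, pose, c(dirs$az[d], dirs$el[d]), m, spec)
        for (r in seq_len(spec$n_repeats)) {
          w <- synth_wave(comp, spec, call, pickup)
          i <- row_of[d, r]
          profiles[i, ] <- profiles[i, ] +
            wave_profile(w, spec, params, blank_duration)
          n_trains <- n_trains + 1L
        }
      }
    }
  })
  profiles <- profiles / spec$n_mics
  values <- profiles_to_templates(profiles, pm, spec, sample_interval)
  g <- spec$grid$directions
  set <- new_template_set(values,
                          data.frame(position_index = position_index,
                                     direction_index = g$direction_index,
                                     az = g$az, el = g$el),
                          spec$grid, sample_interval)
  attr(set, "counts") <- list(n_echo_trains = n_trains,
                              n_profiles = nrow(pm),
                              n_templates = nrow(values))
  set
}

#' Simulate templates for a whole sampling design
#'
#' Streams [simulate_position_templates()] over every pose of a design. Each
#' position can have its own scene (isolated spots) or all positions can
#' share one scene (a transect through a corridor).
#'
#' @param scenes a single `scene` or a list of scenes, one per pose.
#' @param design a `sampling_design`.
#' @param spec a [device_spec()].
#' @param rng_seed integer; per-position seeds are derived from it.
#' @param ... passed to [simulate_position_templates()].
#' @return a `template_set` covering all positions.
#' @export
simulate_design_templates <- function(scenes, design, spec, rng_seed = 1, ...) {
  npos <- nrow(design$poses)
  if (inherits(scenes, "scene")) scenes <- rep(list(scenes), npos)
  stopifnot(length(scenes) == npos)
  sets <- lapply(seq_len(npos), function(p) {
    simulate_position_templates(scenes[[p]], design$poses[p, ], spec,
                                rng_seed = (rng_seed %% 1000003L) * 1000L + p,
                                position_index = p, ...)
  })
  out <- do.call(combine_template_sets, c(sets, list(renumber = FALSE)))
  out$design_name <- design$design_name
  out$spacing <- design$spacing
  out
}
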