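# Small device configurations and scene builders shared across tests.
# Unit tests use a short recording window and a coarse grid so the auditory
# model runs in milliseconds; the acceptance tests use the canonical device.

tiny_spec <- function(n_mics = 2, n_repeats = 3, self_noise_level = 0.002,
                      record_duration = 8e-3,
                      grid = direction_grid(seq(-20, 20, by = 10),
                                            c(-14.2, -3.4, 7.4))) {
  device_spec(record_duration = record_duration, n_mics = n_mics,
              mic_offsets = mic_array(n_mics), grid = grid,
              n_repeats = n_repeats, self_noise_level = self_noise_level)
}

point_scene <- function(x, y, z, strength = 1) {
  structure(list(reflectors = data.frame(x = x, y = y, z = z,
                                         strength = strength,
                                         kind = "point-scatterer"),
                 archetype = "fixture", rng_seed = 0L),
            class = "scene")
}

empty_scene <- function() generate_scene("open", rng_seed = 1)

# template set fixture from a bare value matrix laid out on a grid
fixture_set <- function(values, az, el, position_index = 1L, grid = NULL,
                        spacing = NA_real_,
                        design_name = if (is.na(spacing)) "spots" else "transect") {
  if (is.null(grid)) grid <- direction_grid(sort(unique(az)), sort(unique(el)))
  d <- grid$directions
  di <- vapply(seq_along(az), function(i) {
    d$direction_index[d$az == az[i] & d$el == el[i]]
  }, integer(1))
  meta <- data.frame(position_index = position_index, direction_index = di,
                     az = az, el = el)
  set <- echoplace:::new_template_set(values, meta, grid,
                                      design_name = design_name,
                                      spacing = spacing)
  set
}

# independent brute-force catchment scanner: maximal prefix whose steps never
# drop by more than tol*M, then the largest separation in it reaching min*M
brute_catchment <- function(dis, sep, M, tol = 0.01, mn = 0.10) {
  run <- 1
  for (k in 2:length(dis)) {
    if (dis[k] < dis[k - 1] - tol * M) break
    run <- k
  }
  best <- 0
  for (k in 1:run) if (dis[k] >= mn * M && sep[k] > best) best <- sep[k]
  best
}

# onset-lag of the strongest echo via sliding inner product with the call,
# skipping the saturated pickup region (independent delay oracle)
echo_onset_sample <- function(waveform, call, skip = 300) {
  n <- length(waveform)
  ks <- skip:(n - length(call))
  sc <- vapply(ks, function(k) sum(call * waveform[k:(k + length(call) - 1)]),
               numeric(1))
  ks[which.max(sc)]
}
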