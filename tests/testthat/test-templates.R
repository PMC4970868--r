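test_that("onset blanking zeroes exactly the samples earlier than 5.8 ms", {
  # 5.8 ms at 219 kS/s covers 1270.2 sample intervals -> 1271 samples blanked
  expect_identical(echoplace:::blank_samples(5.8e-3, 219000), 1271L)
  # blanked window corresponds to about 1 m of two-way travel
  expect_equal(343 * 5.8e-3 / 2, 1, tolerance = 0.01)
  p <- auditory_params(219000)
  withr::with_seed(2, w <- rnorm(2000, 0, 0.01))
  cg <- dechirp(cochleogram(w, p, sample_rate = 219000))
  b <- blank_onset(cg, 2e-3)
  ns <- echoplace:::blank_samples(2e-3, 219000)
  expect_true(all(b$activations[, seq_len(ns)] == 0))
  expect_equal(b$activations[, (ns + 1):2000], cg$activations[, (ns + 1):2000])
  expect_equal(blank_onset(cg, 0)$activations, cg$activations)
  expect_error(blank_onset(cg, 1), "record")
})

test_that("downsampling integrates over 350 us bins and drops the partial tail", {
  v <- downsample_profile(rep(2.5, 7446), 219000)
  expect_identical(length(v), 97L)   # floor(34 ms / 350 us)
  expect_true(all(abs(v - 2.5) < 1e-12))
  expect_true(all(downsample_profile(rep(0, 7446), 219000) == 0))
  # a linear ramp downsamples to the ramp value at the bin centres
  ramp <- seq(0, 1, length.out = 7446)
  d <- downsample_profile(ramp, 219000)
  centres <- (seq_len(97) - 0.5) * 350e-6
  expected <- centres / (7445 / 219000)
  expect_true(all(abs(d - expected) < 1 / 7445))
})

test_that("the 3x3 neighbourhood average truncates at grid edges", {
  grid <- direction_grid(seq(0, 40, by = 10), c(0, 10.8, 21.6))
  nd <- nrow(grid$directions)
  meta <- data.frame(direction_index = seq_len(nd), repeat_index = 1L)
  profiles <- matrix(seq_len(nd), ncol = 1)  # profile value = direction index
  out <- spatial_average(profiles, meta, grid)
  d <- grid$directions
  manual <- function(i) {
    nb <- which(abs(d$az_idx - d$az_idx[i]) <= 1 & abs(d$el_idx - d$el_idx[i]) <= 1)
    mean(nb)
  }
  corner <- which(d$az_idx == 1 & d$el_idx == 1)
  interior <- which(d$az_idx == 3 & d$el_idx == 2)
  nb_corner <- which(abs(d$az_idx - 1) <= 1 & abs(d$el_idx - 1) <= 1)
  nb_inter <- which(abs(d$az_idx - 3) <= 1 & abs(d$el_idx - 2) <= 1)
  expect_identical(length(nb_corner), 4L)
  expect_identical(length(nb_inter), 9L)
  expect_equal(out[corner, 1], manual(corner))
  expect_equal(out[interior, 1], manual(interior))
  # direction-uniform data is a fixed point
  uni <- matrix(7, nrow = nd, ncol = 3)
  expect_equal(spatial_average(uni, meta, grid), uni)
})

test_that("collapse averages channels and microphones per (direction, repeat) cell", {
  spec <- tiny_spec(n_mics = 2, n_repeats = 2,
                    grid = direction_grid(c(0, 10), c(0, 10.8)))
  nd <- 4L
  make_cg <- function(value) {
    structure(list(activations = matrix(value, nrow = 3, ncol = 6),
                   center_frequencies = c(30, 35, 40), sample_rate = 219000,
                   dechirped = TRUE),
              class = "cochleogram")
  }
  meta <- expand.grid(direction_index = 1:nd, mic_index = 1:2,
                      repeat_index = 1:2)
  cgs <- lapply(seq_len(nrow(meta)), function(i) make_cg(meta$mic_index[i]))
  out <- collapse(cgs, meta, spec)
  expect_identical(nrow(out$profiles), nd * 2L)  # directions x repeats
  expect_true(all(abs(out$profiles - 1.5) < 1e-12))  # mean of mic values 1, 2
  # microphone order must not matter
  perm <- order(meta$repeat_index, meta$direction_index, -meta$mic_index)
  out2 <- collapse(cgs[perm], meta[perm, ], spec)
  expect_equal(out2$profiles[order(out2$meta$direction_index, out2$meta$repeat_index), ],
               out$profiles[order(out$meta$direction_index, out$meta$repeat_index), ])
  # a missing cell is reported by name
  expect_error(collapse(cgs[-1], meta[-1, ], spec), "missing")
})

test_that("the fused per-echo path equals the composed pipeline stages", {
  spec <- tiny_spec(self_noise_level = 0.002)
  p <- auditory_params(spec$sample_rate)
  scn <- point_scene(c(1.2, 2.5), c(0, 0.4), c(0, -0.2), strength = c(1, 0.7))
  et <- synthesize_echo_train(scn, c(0, 0, 0), c(0, -3.4), 1, spec, rng_seed = 9)
  fused <- echoplace:::wave_profile(et$waveform, spec, p, 5.8e-3)
  composed <- colMeans(blank_onset(dechirp(cochleogram(et, p)), 5.8e-3)$activations)
  expect_equal(fused, composed, tolerance = 1e-12)
})

test_that("templates scale by a^0.4 when all input waveforms scale by a", {
  spec <- tiny_spec(self_noise_level = 0)
  design <- spots_design(matrix(0, 1, 3))
  ds <- generate_dataset(point_scene(1.5, 0.2, 0), design, spec, rng_seed = 1)
  t1 <- build_templates(ds)
  ds$waves <- 2 * ds$waves
  t2 <- build_templates(ds)
  expect_equal(t2$values, 2^0.4 * t1$values, tolerance = 1e-9)
})

test_that("build_templates honours the per-stage count contracts at small scale", {
  spec <- tiny_spec()
  design <- transect_design(2, 0.3)
  ds <- generate_dataset(point_scene(2, 1, 0), design, spec, rng_seed = 3)
  tpl <- build_templates(ds)
  nd <- nrow(spec$grid$directions)
  expect_identical(nrow(tpl$values), 2L * nd)
  expect_false(anyDuplicated(tpl$meta[, c("position_index", "direction_index")]) > 0)
  expect_true(all(is.finite(tpl$values)) && all(tpl$values >= 0))
})

test_that("streaming and materialized template construction agree", {
  spec <- tiny_spec()
  scn <- point_scene(c(1.8, 2.2), c(-0.5, 1), c(0, 0.3), strength = c(1, 2))
  ds <- generate_dataset(scn, spots_design(matrix(0, 1, 3)), spec, rng_seed = 11)
  a <- build_templates(ds)
  b <- simulate_position_templates(scn, c(0, 0, 0), spec, rng_seed = 11)
  expect_equal(a$values, b$values, tolerance = 1e-12)
  cnt <- attr(b, "counts")
  nd <- nrow(spec$grid$directions)
  expect_identical(cnt$n_echo_trains, as.integer(nd * spec$n_mics * spec$n_repeats))
  expect_identical(cnt$n_profiles, as.integer(nd * spec$n_repeats))
  expect_identical(cnt$n_templates, as.integer(nd))
})

test_that("full-length recordings produce 97-sample templates", {
  spec <- device_spec(n_mics = 1, mic_offsets = mic_array(1),
                      grid = direction_grid(c(-10, 0, 10), c(-3.4, 7.4)),
                      n_repeats = 1)
  st <- simulate_position_templates(point_scene(2, 0, 0), c(0, 0, 0), spec,
                                    rng_seed = 2)
  expect_identical(ncol(st$values), 97L)
})
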