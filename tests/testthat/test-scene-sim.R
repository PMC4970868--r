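test_that("open scenes contain no reflector; unknown archetypes are rejected", {
  scn <- generate_scene("open", density = 10, rng_seed = 1)
  expect_identical(nrow(scn$reflectors), 0L)
  expect_error(generate_scene("swamp"), "arg")
})

test_that("cluttered scenes are a homogeneous Poisson draw at the given density", {
  region <- list(xlim = c(0, 5), ylim = c(0, 2), zlim = c(0, 1))  # 10 m^3
  counts <- vapply(1:1000, function(s) {
    nrow(generate_scene("cluttered", density = 5, region = region,
                        rng_seed = s)$reflectors)
  }, numeric(1))
  # mean of Poisson(50) over 1000 seeds; 3 standard errors ~ 0.67
  expect_lt(abs(mean(counts) - 50), 1)
  expect_gt(var(counts), 25)  # Poisson, not deterministic
})

test_that("scene generation is deterministic for a fixed seed", {
  a <- generate_scene("semi-cluttered", 0.5, rng_seed = 7)
  b <- generate_scene("semi-cluttered", 0.5, rng_seed = 7)
  expect_identical(a, b)
  d <- generate_scene("semi-cluttered", 0.5, rng_seed = 8)
  expect_false(identical(a$reflectors, d$reflectors))
})

test_that("beam gain is normalized, tapered and hits -3 dB at the half width", {
  spec <- device_spec()
  expect_equal(beam_gain(0, 55, spec), 1)
  expect_equal(beam_gain(10, 55, spec), 10^(-3 / 20), tolerance = 1e-12)
  expect_gte(beam_gain(5, 55, spec), beam_gain(15, 55, spec))
  offs <- seq(0, 60, by = 2.5)
  g <- beam_gain(offs, 70, spec)
  expect_true(all(diff(g) < 0))
  expect_true(all(g > 0 & g <= 1))
  expect_error(beam_gain(5, 120, spec), "sweep")
})

test_that("echo delay matches two-way travel time within one sample", {
  spec <- tiny_spec(self_noise_level = 0, record_duration = 20e-3)
  call <- call_waveform(spec)
  for (r in c(1, 2, 2.7)) {
    scn <- point_scene(r, 0, 0)
    et <- synthesize_echo_train(scn, c(0, 0, 0), c(0, -3.4), 1, spec)
    onset <- echo_onset_sample(et$waveform, call)
    expect_lt(abs((onset - 1) - 2 * r / spec$c * spec$sample_rate), 1.5)
  }
})

test_that("echo amplitude follows two-way spherical spreading", {
  spec <- tiny_spec(self_noise_level = 0, record_duration = 20e-3)
  a <- function(r) {
    et <- synthesize_echo_train(point_scene(r, 0, 0), c(0, 0, 0), c(0, -3.4),
                                1, spec)
    max(abs(et$waveform[800:length(et$waveform)]))
  }
  expect_equal(a(1) / a(2), 4, tolerance = 0.01)
})

test_that("symmetric off-boresight reflectors return equal echo amplitudes", {
  spec <- tiny_spec(self_noise_level = 0, record_duration = 20e-3)
  r <- 2
  ang <- 5 * pi / 180
  amp_at <- function(y) {
    et <- synthesize_echo_train(point_scene(r * cos(ang), y, 0), c(0, 0, 0),
                                c(0, 0), 1,
                                tiny_spec(self_noise_level = 0,
                                          record_duration = 20e-3,
                                          grid = direction_grid(0, 0)))
    max(abs(et$waveform[800:length(et$waveform)]))
  }
  expect_equal(amp_at(r * sin(ang)), amp_at(-r * sin(ang)), tolerance = 1e-12)
})

test_that("empty scenes give pickup followed by device noise only", {
  spec <- tiny_spec(self_noise_level = 0)
  et <- synthesize_echo_train(empty_scene(), c(0, 0, 0), c(0, -3.4), 1, spec)
  ncall <- round(spec$call_duration * spec$sample_rate)
  expect_true(all(et$waveform[(ncall + 1):spec$n_samples] == 0))
  expect_gt(max(abs(et$waveform[1:ncall])), 0)
})

test_that("synthesis is bit-identical for identical seeds", {
  spec <- tiny_spec()
  scn <- point_scene(2, 0.3, -0.2)
  a <- synthesize_echo_train(scn, c(0, 0, 0), c(10, -3.4), 2, spec, rng_seed = 5)
  b <- synthesize_echo_train(scn, c(0, 0, 0), c(10, -3.4), 2, spec, rng_seed = 5)
  expect_identical(a$waveform, b$waveform)
  d <- synthesize_echo_train(scn, c(0, 0, 0), c(10, -3.4), 2, spec, rng_seed = 6)
  expect_false(identical(a$waveform, d$waveform))
})

test_that("degenerate geometry and off-grid directions are rejected", {
  spec <- tiny_spec()
  expect_error(synthesize_echo_train(point_scene(0, 0, 0), c(0, 0, 0),
                                     c(0, -3.4), 1, spec), "degenerate")
  expect_error(synthesize_echo_train(empty_scene(), c(0, 0, 0), c(7, 2), 1,
                                     spec), "grid")
})

test_that("datasets satisfy the position x direction x repeat x mic count contract", {
  spec <- tiny_spec()
  design <- transect_design(3, 0.25)
  ds <- generate_dataset(point_scene(2, 1, 0), design, spec, rng_seed = 1)
  nd <- nrow(spec$grid$directions)
  expect_identical(ncol(ds$waves), as.integer(3 * nd * spec$n_repeats * spec$n_mics))
  expect_identical(nrow(unique(ds$meta)), ncol(ds$waves))
  cnt <- dataset_counts(design, spec)
  expect_identical(cnt$total, as.integer(3 * nd * spec$n_repeats * spec$n_mics))
  # repeats differ only in the noise realization
  spec0 <- tiny_spec(self_noise_level = 0)
  ds0 <- generate_dataset(point_scene(2, 1, 0), design, spec0, rng_seed = 1)
  r1 <- ds0$meta$repeat_index == 1
  r2 <- ds0$meta$repeat_index == 2
  expect_identical(ds0$waves[, r1], ds0$waves[, r2])
})

test_that("transect designs are collinear and evenly spaced", {
  d <- transect_design(5, 0.2, origin = c(1, 1, 0), axis = c(0, 1, 0))
  steps <- diff(d$poses)
  expect_true(all(abs(steps[, 2] - 0.2) < 1e-12))
  expect_true(all(abs(steps[, c(1, 3)]) < 1e-12))
})
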