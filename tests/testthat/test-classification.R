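test_that("the noise floor is the global maximum over reflector-free templates", {
  g <- direction_grid(c(0, 10), 0)
  s1 <- fixture_set(matrix(c(0.1, 0.3, 0.2, 0.05), 2), c(0, 10), c(0, 0))
  s2 <- fixture_set(matrix(c(0.25, 0.0, 0.1, 0.2), 2), c(0, 10), c(0, 0))
  expect_equal(estimate_noise_floor(list(s1, s2)), 0.3)
  expect_equal(estimate_noise_floor(list(s2, s1)), 0.3)
  expect_equal(estimate_noise_floor(fixture_set(matrix(0, 2, 4), c(0, 10), c(0, 0))), 0)
  expect_error(estimate_noise_floor(list()), "no reflector-free")
})

test_that("flooring clamps from below and is idempotent", {
  expect_equal(apply_floor(c(0, 0.2, 0.5), 0.3), c(0.3, 0.3, 0.5))
  expect_equal(apply_floor(c(0, 0.2, 0.5), 0), c(0, 0.2, 0.5))
  expect_equal(apply_floor(apply_floor(c(0, 0.2, 0.5), 0.3), 0.3),
               apply_floor(c(0, 0.2, 0.5), 0.3))
  s <- fixture_set(matrix(c(0.1, 0.4), 1), 0, 0, grid = direction_grid(0, 0))
  expect_equal(apply_floor(s, 0.2)$values, matrix(c(0.2, 0.4), 1))
})

test_that("the Mahalanobis distance with isotropic noise is Euclidean over sigma_n", {
  t0 <- rep(0, 97)
  t1 <- c(3, 4, rep(0, 95))
  expect_equal(template_distance(t1, t0, 1), 5)
  expect_equal(template_distance(t1, t1, 2.3), 0)
  expect_equal(template_distance(t1, t0, 4), 5 / 2)  # sigma_n = 2
  expect_error(template_distance(t1, t0, 0), "positive")
})

test_that("sigma calibration inverts the two-alternative closed form", {
  d75 <- 2 * qnorm(0.75)  # 1.349
  t_ref <- c(d75, rep(0, 96))
  t_sib <- rep(0, 97)
  cal <- calibrate_sigma(t_ref, t_sib, 0.75)
  expect_equal(cal$sigma_n, 1, tolerance = 1e-12)
  cal2 <- calibrate_sigma(2 * t_ref, t_sib * 2, 0.75)
  expect_equal(cal2$sigma_n, 2, tolerance = 1e-12)
  expect_error(calibrate_sigma(t_ref, t_sib, 0.5), "criterion")
  expect_error(calibrate_sigma(t_ref, t_sib, 1), "criterion")
  # Monte-Carlo verification of the criterion at the calibrated variance
  rate <- two_class_rate(t_ref, t_sib, cal$sigma_n2, n_draws = 2e4,
                         rng_seed = 4)
  expect_lt(abs(rate - 0.75), 3 * sqrt(0.75 * 0.25 / 4e4))
})

test_that("nearest-template classification matches the Gaussian two-class oracle", {
  d <- 1.349
  X <- rbind(c(d, rep(0, 9)), rep(0, 10))
  set <- fixture_set(X, c(0, 10), c(0, 0))
  nm <- noise_model(0, 1)
  cp <- classify_prob(set, 1, nm, max_draws = 5000, min_draws = 5000, tol = 0,
                      rng_seed = 21)
  expect_lt(abs(cp$pc - pnorm(d / 2)), 3 * sqrt(0.75 * 0.25 / 5000))
  expect_equal(sum(cp$posterior), 1, tolerance = 1e-9)
  expect_equal(unname(cp$posterior["1"]), cp$pc)
})

test_that("identical templates split the posterior uniformly", {
  N <- 5
  X <- matrix(0.2, nrow = N, ncol = 8)
  set <- fixture_set(X, seq(0, 40, by = 10), rep(0, N))
  nm <- noise_model(0, 1)
  cp <- classify_prob(set, 3, nm, max_draws = 4000, min_draws = 4000, tol = 0,
                      rng_seed = 8)
  expect_lt(abs(cp$pc - 1 / N), 3 * sqrt((1 / N) * (1 - 1 / N) / 4000))
})

test_that("well-separated templates classify almost surely", {
  X <- diag(25, 4)[, c(1:4, rep(4, 6))]  # pairwise distance 25 * sqrt(2) > 20
  set <- fixture_set(X, seq(0, 30, by = 10), rep(0, 4))
  nm <- noise_model(0, 1)
  cp <- classify_prob(set, 2, nm, max_draws = 1000, min_draws = 1000, tol = 0,
                      rng_seed = 2)
  expect_gte(cp$pc, 0.999)
})

test_that("pc does not increase with the noise variance", {
  withr::with_seed(10, X <- matrix(rnorm(6 * 12), nrow = 6))
  set <- fixture_set(X, seq(0, 50, by = 10), rep(0, 6))
  pcs <- vapply(c(0.25, 1, 4, 16), function(s2) {
    classify_prob(set, 1, noise_model(0, s2), max_draws = 3000,
                  min_draws = 3000, tol = 0, rng_seed = 5)$pc
  }, numeric(1))
  mc_slack <- 3 * sqrt(0.25 / 3000)
  expect_true(all(diff(pcs) < mc_slack))
})

test_that("classification stops between the replication bounds once converged", {
  X <- rbind(c(30, rep(0, 9)), rep(0, 10))
  set <- fixture_set(X, c(0, 10), c(0, 0))
  cp <- classify_prob(set, 1, noise_model(0, 1), rng_seed = 3)
  expect_gte(cp$n_draws, 100)
  expect_lte(cp$n_draws, 1000)
})

test_that("great-circle separation behaves on the sphere", {
  expect_lt(great_circle(c(12, 5), c(12, 5)), 1e-5)
  expect_equal(great_circle(c(0, 0), c(90, 0)), 90)
  expect_equal(great_circle(c(0, -25), c(0, 40)), 65)
  expect_equal(great_circle(c(0, 0), c(180, 0)), 180)
  # azimuth separation shrinks with elevation
  expect_lt(great_circle(c(0, 60), c(30, 60)), 30)
})

test_that("the angular error is the posterior-weighted great-circle distance", {
  X <- matrix(0, nrow = 3, ncol = 5)
  set <- fixture_set(X, c(0, 90, 0), c(0, 0, 40),
                     grid = direction_grid(c(0, 90), c(0, 40)))
  p_delta <- stats::setNames(c(1, 0, 0), 1:3)
  expect_equal(angular_error(p_delta, set, 1), 0, tolerance = 1e-5)
  p_half <- stats::setNames(c(0.5, 0.5, 0), 1:3)
  expect_equal(angular_error(p_half, set, 1), 45, tolerance = 1e-5)
  # uniform posterior over the panorama equals the brute-force mean distance
  p_unif <- stats::setNames(rep(1 / 3, 3), 1:3)
  brute <- mean(c(great_circle(c(0, 0), c(0, 0)),
                  great_circle(c(0, 0), c(90, 0)),
                  great_circle(c(0, 0), c(0, 40))))
  expect_equal(angular_error(p_unif, set, 1), brute, tolerance = 1e-5)
})

test_that("cross-position confusion is zero for one position and halves pc for duplicates", {
  withr::with_seed(13, X <- matrix(rnorm(4 * 10, sd = 5), nrow = 4))
  one <- fixture_set(X, seq(0, 30, 10), rep(0, 4))
  nm <- noise_model(0, 1)
  cc1 <- cross_position_confusion(one, nm, rng_seed = 2,
                                  max_draws = 500, min_draws = 500, tol = 0)
  expect_true(all(cc1$delta_pc == 0))
  # duplicating every template at a second position halves pc globally
  dup <- combine_template_sets(one, one)
  cc2 <- cross_position_confusion(dup, nm, rng_seed = 2,
                                  max_draws = 2000, min_draws = 2000, tol = 0)
  expect_equal(mean(cc2$pc_global) / mean(cc2$pc_within), 0.5, tolerance = 0.05)
})
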