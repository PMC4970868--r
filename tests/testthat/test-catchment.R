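test_that("median pairwise dissimilarity follows its definition", {
  two <- fixture_set(rbind(c(5, 0), c(0, 0)), c(0, 10), c(0, 0))
  expect_equal(median_pairwise_dissimilarity(two, 1), 5)
  same <- fixture_set(matrix(1, 3, 4), c(0, 10, 20), c(0, 0, 0))
  expect_equal(median_pairwise_dissimilarity(same, 1), 0)
  # three pairwise distances {1, 2, sqrt(5)} -> median 2
  tri <- fixture_set(rbind(c(0, 0), c(1, 0), c(0, 2)), c(0, 10, 20), rep(0, 3))
  expect_equal(median_pairwise_dissimilarity(tri, 1), 2)
  # Mahalanobis scaling
  expect_equal(median_pairwise_dissimilarity(tri, 4), 1)
  expect_error(median_pairwise_dissimilarity(fixture_set(matrix(1, 1, 2), 0, 0,
                                             grid = direction_grid(0, 0)), 1),
               "two templates")
})

test_that("the monotone run honours the 1% dip tolerance and the 10% floor", {
  M <- 1
  sep <- 0:3
  expect_equal(monotone_run_length(c(0, 0.2, 0.5, 1.0), sep, M), 3)
  expect_equal(monotone_run_length(c(0, 0.02, 0.05, 0.08), sep, M), 0)
  # a 0.5% dip does not end the run
  expect_equal(monotone_run_length(c(0, 0.3, 0.295, 0.6), sep, M), 3)
  # a 2% dip does
  expect_equal(monotone_run_length(c(0, 0.3, 0.28, 0.6), sep, M), 1)
  # the largest qualifying separation may precede the run end
  expect_equal(monotone_run_length(c(0, 0.5, 0.505, 0.09), sep, M), 2)
})

test_that("monotone_run_length agrees with a brute-force scanner on random curves", {
  withr::with_seed(99, {
    for (i in seq_len(2000)) {
      n <- sample(3:12, 1)
      dis <- c(0, abs(cumsum(rnorm(n, 0.04, 0.12))))
      sep <- c(0, sort(runif(n, 0.1, 5)))
      M <- runif(1, 0.5, 2)
      expect_identical(monotone_run_length(dis, sep, M),
                       brute_catchment(dis, sep, M))
    }
  })
})

test_that("catchment distances are invariant to joint template/noise rescaling", {
  withr::with_seed(31, X <- matrix(abs(rnorm(36 * 12)), nrow = 36))
  az <- rep(seq(0, 50, 10), 6)
  pos <- rep(1:6, each = 6)
  set <- fixture_set(X, az, rep(0, 36), position_index = pos, spacing = 0.5)
  a <- linear_catchment(set, sigma_n2 = 1)
  set2 <- set
  set2$values <- 10 * set2$values
  b <- linear_catchment(set2, sigma_n2 = 100)
  expect_equal(a$per_template$catchment_m, b$per_template$catchment_m)
  expect_equal(a$M, b$M)  # Mahalanobis: the normalizer is scale-free too
})

test_that("angular catchment: flat panoramas give zero, monotone ones reach the edge", {
  g <- direction_grid(seq(0, 90, by = 10), 0)
  same <- fixture_set(matrix(1, 10, 5), g$directions$az, g$directions$el, grid = g)
  flat <- angular_catchment(same, 1, M = 1)
  expect_true(all(flat$catchment$catchment_deg == 0))
  expect_true(all(flat$profiles[[1]]$dissimilarity == 0))
  # dissimilarity equal to angular separation by construction
  mono <- fixture_set(matrix(g$directions$az, ncol = 1), g$directions$az,
                      g$directions$el, grid = g)
  ac10 <- angular_catchment(mono, 1, bin_width = 10)
  expect_equal(ac10$catchment$catchment_deg, 90)
  # halving the bin width does not change the catchment of a monotone curve
  ac5 <- angular_catchment(mono, 1, bin_width = 5)
  expect_equal(ac5$catchment$catchment_deg, 90)
})

test_that("linear catchment: uniform transects give zero, monotone ones reach the ends", {
  g <- direction_grid(c(0, 10), 0)
  npos <- 6
  az <- rep(c(0, 10), npos)
  pos <- rep(1:npos, each = 2)
  same <- fixture_set(matrix(2, 2 * npos, 4), az, rep(0, 2 * npos),
                      position_index = pos, spacing = 0.25)
  # all templates equal: M = 0 and every catchment 0
  lc0 <- linear_catchment(same, 1, M = 1)
  expect_true(all(lc0$per_template$catchment_m == 0))
  # template value = position coordinate: dissimilarity = separation
  vals <- matrix(rep((1:npos) * 0.25, each = 2), ncol = 1)
  mono <- fixture_set(vals, az, rep(0, 2 * npos), position_index = pos,
                      spacing = 0.25)
  lc <- linear_catchment(mono, 1)
  per <- lc$per_template
  span <- (npos - 1) * 0.25
  for (x in 1:npos) {
    expected <- max(x - 1, npos - x) * 0.25
    expect_true(all(per$catchment_m[per$position_index == x] == expected))
  }
  expect_true(all(per$catchment_m[per$position_index %in% c(1, npos)] == span))
  expect_identical(nrow(lc$per_direction), 2L)
  expect_error(linear_catchment(fixture_set(matrix(1, 2, 3), c(0, 0), c(0, 0),
                                            position_index = 1:2,
                                            spacing = 0.5), 1),
               "three")
})

test_that("the trade-off report handles degenerate and two-site inputs", {
  df_const <- data.frame(pc = rep(0.5, 10), catchment_m = runif(10),
                         site = rep(c("a", "b"), 5))
  tr <- tradeoff_report(df_const)
  expect_true(is.na(tr$correlation$rho))
  expect_match(tr$correlation$note, "degenerate")
  withr::with_seed(7, {
    x <- runif(40)
    df_neg <- data.frame(pc = 1 - x + rnorm(40, 0, 0.05), catchment_m = x,
                         site = rep(c("a", "b"), each = 20))
  })
  tr2 <- tradeoff_report(df_neg)
  expect_lt(tr2$correlation$rho, 0)
  # identical samples at both sites: rank-sum finds nothing
  df_same <- data.frame(pc = rep(seq(0, 1, length.out = 10), 2),
                        catchment_m = rep(seq(1, 2, length.out = 10), 2),
                        site = rep(c("a", "b"), each = 10))
  tr3 <- tradeoff_report(df_same)
  expect_gt(tr3$ranksum_catchment$p, 0.9)
  expect_gt(tr3$ranksum_pc$p, 0.9)
})
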