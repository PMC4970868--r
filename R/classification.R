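#' Noise model for template classification
#'
#' Two noise sources limit what a template can encode: a noise floor `n_f`
#' (the device's internal noise produces non-zero template values even with
#' no reflector; values below `n_f` carry no scene information) and
#' independent Gaussian perceptual noise with variance `sigma_n2` on every
#' template sample, calibrated so that two single-echo templates differing by
#' `jnd_db` decibels are discriminated at the `criterion` correct rate.
#'
#' @param n_f noise floor, template units (>= 0).
#' @param sigma_n2 Gaussian noise variance, template units squared (> 0).
#' @param jnd_db just-noticeable echo intensity difference, dB.
#' @param criterion two-alternative correct-classification criterion.
#' @return an object of class `noise_model`.
#' @export
noise_model <- function(n_f, sigma_n2, jnd_db = 2, criterion = 0.75) {
  stopifnot(n_f >= 0, sigma_n2 > 0)
  structure(list(n_f = n_f, sigma_n2 = sigma_n2, jnd_db = jnd_db,
                 criterion = criterion),
            class = "noise_model")
}

#' Estimate the noise floor from reflector-free templates
#'
#' The floor is the global maximum template value over measurements taken
#' with no reflector in range (device pointed at empty space), processed by
#' the full template pipeline.
#'
#' @param sets one `template_set` or a list of them, all reflector-free.
#' @return `n_f`, a scalar.
#' @export
estimate_noise_floor <- function(sets) {
  if (inherits(sets, "template_set")) sets <- list(sets)
  if (length(sets) == 0) stop("no reflector-free templates supplied")
  max(vapply(sets, function(s) max(s$values), numeric(1)))
}

#' Floor a template set
#'
#' Every value below `n_f` is set to `n_f` (it carries no information beyond
#' the absence of an echo). Idempotent.
#'
#' @param set a `template_set` (or bare numeric vector/matrix).
#' @param n_f the noise floor.
#' @return the floored object, same shape.
#' @export
apply_floor <- function(set, n_f) {
  if (inherits(set, "template_set")) {
    set$values <- pmax(set$values, n_f)
    set
  } else {
    pmax(set, n_f)
  }
}

#' Mahalanobis distance between templates
#'
#' With isotropic noise covariance Q = sigma_n2 * I this is the Euclidean
#' distance divided by sigma_n:
#' d = sqrt(sum((t_i - t_j)^2) / sigma_n2).
#'
#' @param t_i,t_j numeric template vectors of equal length.
#' @param sigma_n2 noise variance (> 0).
#' @return non-negative scalar.
#' @export
template_distance <- function(t_i, t_j, sigma_n2) {
  if (sigma_n2 <= 0) stop("sigma_n2 must be positive")
  stopifnot(length(t_i) == length(t_j))
  sqrt(sum((t_i - t_j)^2) / sigma_n2)
}

#' Calibrate the perceptual noise variance from a just-noticeable difference
#'
#' Given templates of two single-echo recordings differing by `jnd_db`
#' decibels in echo intensity, returns the Gaussian noise variance at which
#' the two-alternative correct-classification probability equals
#' `criterion`. For two templates at Mahalanobis distance d the correct rate
#' is Phi(d/2), so sigma_n = ||T_a - T_b|| / (2 * qnorm(criterion)).
#'
#' @param t_ref,t_jnd the two templates (numeric vectors or single-row
#'   `template_set`s); `t_jnd` is built from the same echo scaled by
#'   10^(jnd_db/20) in waveform amplitude.
#' @param criterion correct-classification criterion, in (0.5, 1).
#' @return list with `sigma_n2`, `sigma_n` and `delta_norm` (||T_a - T_b||).
#' @export
calibrate_sigma <- function(t_ref, t_jnd, criterion = 0.75) {
  if (criterion <= 0.5 || criterion >= 1)
    stop("criterion must lie strictly between 0.5 and 1")
  a <- if (inherits(t_ref, "template_set")) as.numeric(t_ref$values) else t_ref
  b <- if (inherits(t_jnd, "template_set")) as.numeric(t_jnd$values) else t_jnd
  delta <- sqrt(sum((a - b)^2))
  if (delta == 0) stop("reference and sibling templates are identical")
  sigma_n <- delta / (2 * qnorm(criterion))
  list(sigma_n2 = sigma_n^2, sigma_n = sigma_n, delta_norm = delta)
}

#' Monte-Carlo two-alternative correct-classification rate
#'
#' Draws noisy copies of each of two templates and classifies each draw to
#' the nearer template by Mahalanobis distance; used to verify the
#' closed-form calibration.
#'
#' @param t_a,t_b numeric template vectors.
#' @param sigma_n2 noise variance.
#' @param n_draws draws per template.
#' @param rng_seed integer seed.
#' @return the correct fraction (scalar in [0, 1]).
#' @export
two_class_rate <- function(t_a, t_b, sigma_n2, n_draws = 1e5, rng_seed = 1) {
  sn <- sqrt(sigma_n2)
  L <- length(t_a)
  withr::with_seed(rng_seed, {
    correct <- 0L
    for (tt in list(list(t_a, t_b), list(t_b, t_a))) {
      own <- tt[[1]]; other <- tt[[2]]
      E <- matrix(rnorm(n_draws * L, 0, sn), nrow = n_draws)
      Tp <- sweep(E, 2, own, "+")
      d_own <- rowSums(E^2)
      d_oth <- rowSums(sweep(Tp, 2, other)^2)
      correct <- correct + sum(d_own < d_oth)
    }
    correct / (2 * n_draws)
  })
}

# nearest-template assignment for a block of noisy draws; exact-tie sets are
# resolved uniformly at random. X is the template matrix (N x L), Tp the
# draws (m x L). Returns assigned template row indices (length m).
assign_nearest <- function(Tp, X, q = rowSums(X^2)) {
  S <- Tp %*% t(X)                      # m x N
  vals <- sweep(2 * S, 2, q)            # -d^2 up to a per-draw constant
  max.col(vals, ties.method = "random")
}

#' Monte-Carlo probability of correct classification for one template
#'
#' Draws noisy re-observations T_i' = T_i + N(0, sigma_n2 I), assigns each
#' to the nearest stored template (Mahalanobis distance; exact ties broken
#' uniformly at random), and returns the fraction assigned to template i
#' together with the full assignment distribution. The estimate is updated
#' every `check_every` draws and stops once the change is below `tol`,
#' bounded by `min_draws` and `max_draws`.
#'
#' @param set a floored `template_set`.
#' @param i row index of the true template in `set`.
#' @param noise a [noise_model()].
#' @param max_draws,min_draws Monte-Carlo replication bounds.
#' @param tol convergence threshold on the running estimate.
#' @param rng_seed integer seed.
#' @param pool optional integer vector of candidate rows (defaults to all);
#'   must contain `i`.
#' @param check_every draws between convergence checks.
#' @return list with `pc`, `posterior` (named assignment frequencies over
#'   `pool`, summing to 1) and `n_draws`.
#' @export
classify_prob <- function(set, i, noise, max_draws = 1000, min_draws = 100,
                          tol = 0.01, rng_seed = 1, pool = NULL,
                          check_every = 50) {
  X <- if (inherits(set, "template_set")) set$values else set
  if (is.null(pool)) pool <- seq_len(nrow(X))
  if (!(i %in% pool)) stop("pool must contain the true template")
  Xp <- X[pool, , drop = FALSE]
  ii <- match(i, pool)
  L <- ncol(Xp)
  sn <- sqrt(noise$sigma_n2)
  q <- rowSums(Xp^2)
  withr::with_seed(rng_seed, {
    counts <- integer(length(pool))
    n <- 0L
    pc_prev <- NA_real_
    while (n < max_draws) {
      m <- min(check_every, max_draws - n)
      E <- matrix(rnorm(m * L, 0, sn), nrow = m)
      Tp <- sweep(E, 2, Xp[ii, ], "+")
      a <- assign_nearest(Tp, Xp, q)
      counts <- counts + tabulate(a, nbins = length(pool))
      n <- n + m
      pc <- counts[ii] / n
      if (n >= min_draws && !is.na(pc_prev) && abs(pc - pc_prev) < tol) break
      pc_prev <- pc
    }
    list(pc = counts[ii] / n,
         posterior = stats::setNames(counts / n, pool),
         n_draws = n)
  })
}

#' Great-circle angular separation between gaze directions
#'
#' Central angle between the unit vectors of two (azimuth, elevation) pairs.
#'
#' @param dir_a,dir_b `c(az, el)` in degrees.
#' @return degrees in [0, 180].
#' @export
great_circle <- function(dir_a, dir_b) {
  ua <- device_basis(dir_a[1], dir_a[2])[, 1]
  ub <- device_basis(dir_b[1], dir_b[2])[, 1]
  acos(pmin(1, pmax(-1, sum(ua * ub)))) * 180 / pi
}

# pairwise great-circle matrix for a set of az/el rows
great_circle_matrix <- function(az, el) {
  azr <- az * pi / 180
  elr <- el * pi / 180
  U <- cbind(cos(elr) * cos(azr), cos(elr) * sin(azr), sin(elr))
  G <- U %*% t(U)
  acos(pmax(pmin(G, 1), -1)) * 180 / pi  # G first: pmin/pmax keep its dim
}

#' Expected angular error of a classified template
#'
#' e_i = sum_c P(T_c | T_i) * g(i, c), the posterior-weighted great-circle
#' distance between the true gaze direction and the direction labels of the
#' templates the noisy draws were assigned to (confusions with templates of
#' other positions contribute via their own direction labels).
#'
#' @param posterior named assignment frequencies over set rows (sums to 1),
#'   as returned by [classify_prob()].
#' @param set the `template_set`.
#' @param i row index of the true template.
#' @return degrees in [0, 180].
#' @export
angular_error <- function(posterior, set, i) {
  rows <- as.integer(names(posterior))
  stopifnot(abs(sum(posterior) - 1) < 1e-9)
  g <- vapply(rows, function(c) {
    great_circle(c(set$meta$az[i], set$meta$el[i]),
                 c(set$meta$az[c], set$meta$el[c]))
  }, numeric(1))
  sum(posterior * g)
}

#' Classify every template of a set
#'
#' Runs [classify_prob()] for each template. By default the candidate pool
#' is restricted to templates of the same position (the panorama the place
#' signature belongs to); set `by_position = FALSE` to classify against the
#' whole set.
#'
#' @param set a floored `template_set`.
#' @param noise a [noise_model()].
#' @param rng_seed integer seed.
#' @param by_position restrict candidate pools to the template's position.
#' @param ... passed to [classify_prob()].
#' @return data.frame: `position_index`, `direction_index`, `az`, `el`,
#'   `pc`, `angular_error`, `n_draws`.
#' @export
classify_set <- function(set, noise, rng_seed = 1, by_position = TRUE, ...) {
  N <- n_templates(set)
  res <- data.frame(position_index = set$meta$position_index,
                    direction_index = set$meta$direction_index,
                    az = set$meta$az, el = set$meta$el,
                    pc = NA_real_, angular_error = NA_real_,
                    n_draws = NA_integer_)
  for (i in seq_len(N)) {
    pool <- if (by_position)
      which(set$meta$position_index == set$meta$position_index[i])
    else seq_len(N)
    cp <- classify_prob(set, i, noise, rng_seed = rng_seed + i, pool = pool, ...)
    res$pc[i] <- cp$pc
    res$angular_error[i] <- angular_error(cp$posterior, set, i)
    res$n_draws[i] <- cp$n_draws
  }
  res
}

#' Confusion leakage across positions
#'
#' For every template, the drop in P_c when the candidate pool grows from
#' the template's own position to all positions in the set:
#' delta_pc = pc(within-position pool) - pc(global pool).
#'
#' @param set a floored multi-position `template_set`.
#' @param noise a [noise_model()].
#' @param rng_seed integer seed (shared per template across both pools).
#' @param ... passed to [classify_prob()].
#' @return data.frame with `pc_within`, `pc_global`, `delta_pc` per template
#'   and attribute `mean_delta`.
#' @export
cross_position_confusion <- function(set, noise, rng_seed = 1, ...) {
  N <- n_templates(set)
  out <- data.frame(position_index = set$meta$position_index,
                    direction_index = set$meta$direction_index,
                    pc_within = NA_real_, pc_global = NA_real_)
  for (i in seq_len(N)) {
    pool <- which(set$meta$position_index == set$meta$position_index[i])
    out$pc_within[i] <- classify_prob(set, i, noise, rng_seed = rng_seed + i,
                                      pool = pool, ...)$pc
    out$pc_global[i] <- classify_prob(set, i, noise, rng_seed = rng_seed + i,
                                      pool = NULL, ...)$pc
  }
  out$delta_pc <- out$pc_within - out$pc_global
  attr(out, "mean_delta") <- mean(out$delta_pc)
  out
}
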