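#' Median pairwise dissimilarity of a template set
#'
#' The median Mahalanobis distance over all unordered template pairs; used
#' as the normalizer M for the 1% dip tolerance and the 10% floor of the
#' catchment rules.
#'
#' @param set a `template_set` (or bare matrix of template rows).
#' @param sigma_n2 noise variance.
#' @return scalar M.
#' @export
median_pairwise_dissimilarity <- function(set, sigma_n2) {
  X <- if (inherits(set, "template_set")) set$values else set
  if (nrow(X) < 2) stop("need at least two templates")
  median(stats::dist(X)) / sqrt(sigma_n2)
}

#' Length of the monotone-increase run of a dissimilarity curve
#'
#' Scans a dissimilarity-vs-separation curve outward from separation 0
#' (where the dissimilarity is 0). The run continues while any decrease
#' between consecutive points is smaller than `tol_frac * M` (1% of the
#' median pairwise dissimilarity by default, allowing for noise). The
#' catchment is the largest separation inside the run whose dissimilarity
#' has reached at least `min_frac * M` (10% by default, so trivial increases
#' never count); 0 if that level is never reached within the run.
#'
#' @param dissimilarities numeric, dissimilarity at each separation;
#'   `dissimilarities[1]` must be 0.
#' @param separations strictly increasing, starting at 0.
#' @param M the median pairwise dissimilarity normalizer.
#' @param tol_frac tolerated dip, as a fraction of M.
#' @param min_frac minimum dissimilarity level, as a fraction of M.
#' @return the catchment separation (same units as `separations`).
#' @export
monotone_run_length <- function(dissimilarities, separations, M,
                                tol_frac = 0.01, min_frac = 0.10) {
  stopifnot(length(dissimilarities) == length(separations),
            separations[1] == 0, dissimilarities[1] == 0,
            !is.unsorted(separations, strictly = TRUE))
  n <- length(separations)
  run_end <- 1L
  while (run_end < n &&
         dissimilarities[run_end + 1] >=
           dissimilarities[run_end] - tol_frac * M) {
    run_end <- run_end + 1L
  }
  ok <- which(dissimilarities[seq_len(run_end)] >= min_frac * M)
  if (length(ok) == 0) return(0)
  separations[max(ok)]
}

#' Angular catchment profiles of panoramic template sets
#'
#' For every position, computes the Mahalanobis dissimilarity between all
#' template pairs of that position's panorama, averages it within
#' great-circle separation bins (default width 10 degrees, the azimuth
#' step), and applies the monotone-run rules to the binned curve. The same
#' 1%/10% rules used for linear catchments are applied by default; set
#' `tol_frac = 0, min_frac = 0` for strict monotonicity.
#'
#' @param set a floored `template_set`.
#' @param sigma_n2 noise variance.
#' @param bin_width separation bin width, degrees.
#' @param M normalizer; defaults to the median pairwise dissimilarity of
#'   `set`.
#' @param tol_frac,min_frac monotone-run rules (fractions of M).
#' @return list with `profiles` (per-position data.frames of `separation`,
#'   `dissimilarity`), `catchment` (data.frame `position_index`,
#'   `catchment_deg`) and `M`.
#' @export
angular_catchment <- function(set, sigma_n2, bin_width = 10, M = NULL,
                              tol_frac = 0.01, min_frac = 0.10) {
  if (is.null(M)) M <- median_pairwise_dissimilarity(set, sigma_n2)
  positions <- sort(unique(set$meta$position_index))
  profiles <- list()
  catch <- numeric(length(positions))
  for (k in seq_along(positions)) {
    rows <- which(set$meta$position_index == positions[k])
    X <- set$values[rows, , drop = FALSE]
    G <- great_circle_matrix(set$meta$az[rows], set$meta$el[rows])
    D <- as.matrix(stats::dist(X)) / sqrt(sigma_n2)
    iu <- upper.tri(G)
    sep <- G[iu]
    dis <- D[iu]
    bin <- ceiling(sep / bin_width)
    bin[bin == 0] <- 1L   # coincident directions at other positions: bin 1
    mdis <- tapply(dis, bin, mean)
    # a bin's separation coordinate is the largest separation attained in it,
    # so the catchment reading is bin-width invariant for monotone curves
    bsep <- as.numeric(tapply(sep, bin, max))
    o <- order(bsep)
    curve <- data.frame(separation = c(0, bsep[o]),
                        dissimilarity = c(0, as.numeric(mdis)[o]))
    profiles[[k]] <- curve
    catch[k] <- monotone_run_length(curve$dissimilarity, curve$separation,
                                    M, tol_frac, min_frac)
  }
  list(profiles = profiles,
       catchment = data.frame(position_index = positions,
                              catchment_deg = catch),
       M = M)
}

#' Linear catchment distances along a transect
#'
#' For each gaze direction and each transect position, evaluates the
#' Mahalanobis dissimilarity to the templates of the same direction at
#' increasing separations |dx| (averaging the two transect directions where
#' both exist; endpoint positions have one-sided curves) and applies the
#' monotone-run rules. The per-direction summary is the median catchment
#' over positions.
#'
#' @param set a floored transect `template_set` (needs `spacing`).
#' @param sigma_n2 noise variance.
#' @param M normalizer; defaults to the median pairwise dissimilarity of
#'   `set`.
#' @param tol_frac,min_frac the 1% dip / 10% floor rules (fractions of M).
#' @return list with `per_template` (data.frame `position_index`,
#'   `direction_index`, `catchment_m`), `per_direction` (data.frame
#'   `direction_index`, `az`, `el`, `median_catchment_m`) and `M`.
#' @export
linear_catchment <- function(set, sigma_n2, M = NULL,
                             tol_frac = 0.01, min_frac = 0.10) {
  spacing <- set$spacing
  if (is.na(spacing)) stop("template set does not come from a transect design")
  positions <- sort(unique(set$meta$position_index))
  npos <- length(positions)
  if (npos < 3) stop("need at least three transect positions")
  if (is.null(M)) M <- median_pairwise_dissimilarity(set, sigma_n2)
  dirs <- sort(unique(set$meta$direction_index))
  rows_pt <- numeric(0)
  out <- list()
  for (d in dirs) {
    rows <- which(set$meta$direction_index == d)
    rows <- rows[order(set$meta$position_index[rows])]
    X <- set$values[rows, , drop = FALSE]
    D <- as.matrix(stats::dist(X)) / sqrt(sigma_n2)
    for (x in seq_len(npos)) {
      dmax <- max(x - 1, npos - x)
      dis <- vapply(seq_len(dmax), function(k) {
        both <- c(if (x - k >= 1) D[x, x - k],
                  if (x + k <= npos) D[x, x + k])
        mean(both)
      }, numeric(1))
      catch <- monotone_run_length(c(0, dis), c(0, seq_len(dmax)) * spacing,
                                   M, tol_frac, min_frac)
      out[[length(out) + 1]] <- data.frame(position_index = positions[x],
                                           direction_index = d,
                                           catchment_m = catch)
    }
  }
  per_template <- do.call(rbind, out)
  med <- tapply(per_template$catchment_m, per_template$direction_index, median)
  dmeta <- set$meta[match(as.integer(names(med)), set$meta$direction_index), ]
  per_direction <- data.frame(direction_index = as.integer(names(med)),
                              az = dmeta$az, el = dmeta$el,
                              median_catchment_m = as.numeric(med))
  list(per_template = per_template, per_direction = per_direction, M = M)
}

#' Trade-off between classifiability and catchment size
#'
#' Rank correlation between per-template P_c and linear catchment distance
#' (pooled over sites), plus Wilcoxon rank-sum comparisons of the two sites'
#' catchments and P_c distributions.
#'
#' @param df data.frame with columns `pc`, `catchment_m` and `site` (a label
#'   with up to two levels), one row per template.
#' @return list with `correlation` (`rho`, `p`, or `NA` with a note when pc
#'   is degenerate) and, when two sites are present, `ranksum_catchment` and
#'   `ranksum_pc` (statistic and p-value).
#' @export
tradeoff_report <- function(df) {
  stopifnot(all(c("pc", "catchment_m", "site") %in% names(df)))
  correlation <- if (length(unique(df$pc)) < 2 ||
                     length(unique(df$catchment_m)) < 2) {
    list(rho = NA_real_, p = NA_real_, note = "degenerate: constant values")
  } else {
    ct <- suppressWarnings(cor.test(df$pc, df$catchment_m,
                                    method = "spearman"))
    list(rho = unname(ct$estimate), p = ct$p.value, note = NULL)
  }
  out <- list(correlation = correlation)
  sites <- unique(df$site)
  if (length(sites) == 2) {
    a <- df$site == sites[1]
    wc <- suppressWarnings(wilcox.test(df$catchment_m[a], df$catchment_m[!a]))
    wp <- suppressWarnings(wilcox.test(df$pc[a], df$pc[!a]))
    out$ranksum_catchment <- list(statistic = unname(wc$statistic),
                                  p = wc$p.value)
    out$ranksum_pc <- list(statistic = unname(wp$statistic), p = wp$p.value)
    out$sites <- sites
  }
  out
}
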