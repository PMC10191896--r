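# Window association scans ----------------------------------------------------
#
# Associations between kidney involvement and each dichotomous
# manifestation are probed region by region on the (x, z) latent plane
# with a signed two-proportion z statistic: positive means the
# manifestation is more frequent among kidney-involved patients in that
# region. Pattern 1 slides an x-axis window of width 0.03 in steps of 0.01
# at a fixed z threshold, comparing the half-plane at/above the threshold
# with the one below; Pattern 2 fixes an x-range and sweeps the z
# threshold. No multiple-testing correction is applied: the curves are
# exploratory descriptives.

#' Rectangular region on the (x, z) feature plane
#'
#' Membership is half-open on both axes: `lo <= coord < hi`. Either bound
#' may be infinite.
#'
#' @param x_lo,x_hi,z_lo,z_hi Interval bounds.
#' @return A list of class `plane_region`.
#' @export
region <- function(x_lo = -Inf, x_hi = Inf, z_lo = -Inf, z_hi = Inf) {
  if (!(x_lo < x_hi) || !(z_lo < z_hi)) {
    abort("region intervals need lo < hi")
  }
  structure(list(x_lo = x_lo, x_hi = x_hi, z_lo = z_lo, z_hi = z_hi),
            class = "plane_region")
}

in_region <- function(embedding, reg) {
  embedding$x >= reg$x_lo & embedding$x < reg$x_hi &
    embedding$z >= reg$z_lo & embedding$z < reg$z_hi
}

#' Scan configuration
#'
#' Defaults follow the published scan settings: window width 0.03, slide
#' step 0.01, the eight z-axis thresholds, and the Pattern-2 x-range
#' \[0.53, 0.60).
#'
#' @param window_width Pattern-1 window extent on the x-axis.
#' @param step Pattern-1 slide increment.
#' @param z_thresholds Z-axis thresholds for Pattern 1 (and the anchor set
#'   for Pattern 2's sweep).
#' @param x_range_pattern2 Fixed x interval of Pattern 2.
#' @param fine_step Spacing of the dense threshold grid Pattern 2 inserts
#'   between the extreme anchors.
#' @param min_group_size Minimum patients per kidney group for a statistic
#'   to be considered defined.
#' @param pooled Use the pooled-variance form of the two-proportion
#'   statistic (default) or the unpooled one.
#' @return A list of class `scan_config`.
#' @export
scan_config <- function(window_width = 0.03,
                        step = 0.01,
                        z_thresholds = c(0.489, 0.490, 0.493, 0.495, 0.496,
                                         0.497, 0.500, 0.510),
                        x_range_pattern2 = c(0.53, 0.60),
                        fine_step = 0.001,
                        min_group_size = 5,
                        pooled = TRUE) {
  if (window_width <= 0 || step <= 0) abort("window_width and step must be positive")
  if (is.unsorted(z_thresholds)) abort("z_thresholds must be sorted ascending")
  structure(list(
    window_width = window_width, step = step,
    z_thresholds = z_thresholds,
    x_range_pattern2 = x_range_pattern2,
    fine_step = fine_step,
    min_group_size = as.integer(min_group_size),
    pooled = pooled
  ), class = "scan_config")
}

#' Two-proportion test statistic
#'
#' Signed z statistic comparing the success proportion of group 1 (kidney
#' involvement present) with group 2 (absent):
#' \deqn{z = (p_1 - p_2) / \sqrt{\hat p (1-\hat p)(1/n_1 + 1/n_2)}}
#' with the pooled proportion \eqn{\hat p = (k_1+k_2)/(n_1+n_2)}. The sign
#' of the statistic equals the sign of \eqn{p_1 - p_2}, so positive values
#' mean the manifestation is more frequent with kidney involvement. The
#' statistic is flagged invalid (NA) when either group is smaller than
#' `min_group_size` or the pooled proportion is degenerate (0 or 1). Its
#' square equals the Pearson chi-square statistic of the 2x2 table without
#' continuity correction.
#'
#' @param k1,n1 Successes and size of group 1. Vectorized.
#' @param k2,n2 Successes and size of group 2.
#' @param min_group_size Validity guard on `n1` and `n2`.
#' @param pooled Pooled-variance (default) or unpooled denominator.
#' @return Tibble: `statistic`, `p1`, `p2`, `n1`, `n2`, `valid`.
#' @export
two_proportion_stat <- function(k1, n1, k2, n2, min_group_size = 5, pooled = TRUE) {
  if (any(c(k1, k2, n1, n2) < 0) || any(k1 > n1) || any(k2 > n2)) {
    abort("counts must satisfy 0 <= k <= n")
  }
  p1 <- ifelse(n1 > 0, k1 / n1, NA_real_)
  p2 <- ifelse(n2 > 0, k2 / n2, NA_real_)
  p_pool <- ifelse(n1 + n2 > 0, (k1 + k2) / (n1 + n2), NA_real_)
  se <- if (pooled) {
    sqrt(p_pool * (1 - p_pool) * (1 / n1 + 1 / n2))
  } else {
    sqrt(p1 * (1 - p1) / n1 + p2 * (1 - p2) / n2)
  }
  valid <- n1 >= min_group_size & n2 >= min_group_size &
    !is.na(p_pool) & p_pool > 0 & p_pool < 1 &
    !is.na(se) & se > 0
  statistic <- ifelse(valid, (p1 - p2) / se, NA_real_)
  tibble::tibble(statistic = statistic, p1 = p1, p2 = p2,
                 n1 = as.integer(n1), n2 = as.integer(n2), valid = valid)
}

#' Association between kidney involvement and a manifestation in a region
#'
#' Restricts to patients inside the region (half-open bounds) and compares
#' the manifestation frequency between the kidney-involved and
#' non-involved patients there. Any upstream exclusion (high anti-dsDNA
#' titers) must already have been applied. Patients with an NA
#' manifestation flag (the "exclude" dichotomization mode) are dropped.
#'
#' @param embedding `latent_embedding` tibble.
#' @param kidney_flags Binary vector, row-aligned with `embedding`.
#' @param manifestation_flags Binary vector, row-aligned.
#' @param reg A [region()].
#' @param config A [scan_config()] (for `min_group_size` and `pooled`).
#' @return One-row tibble as from [two_proportion_stat()].
#' @export
association_in_region <- function(embedding, kidney_flags, manifestation_flags,
                                  reg, config = scan_config()) {
  stopifnot(length(kidney_flags) == nrow(embedding),
            length(manifestation_flags) == nrow(embedding))
  inside <- in_region(embedding, reg) & !is.na(manifestation_flags)
  kid <- kidney_flags[inside]
  man <- manifestation_flags[inside]
  two_proportion_stat(
    k1 = sum(man[kid == 1L]), n1 = sum(kid == 1L),
    k2 = sum(man[kid == 0L]), n2 = sum(kid == 0L),
    min_group_size = config$min_group_size, pooled = config$pooled
  )
}

# shared assembly of one scan position: statistics above and below a z
# threshold within an x interval
scan_position <- function(embedding, kidney_flags, manifestation_flags,
                          x_lo, x_hi, z_threshold, config) {
  above <- association_in_region(
    embedding, kidney_flags, manifestation_flags,
    region(x_lo, x_hi, z_lo = z_threshold), config
  )
  below <- association_in_region(
    embedding, kidney_flags, manifestation_flags,
    region(x_lo, x_hi, z_hi = z_threshold), config
  )
  tibble::tibble(
    stat_above = above$statistic, valid_above = above$valid,
    n1_above = above$n1, n2_above = above$n2,
    stat_below = below$statistic, valid_below = below$valid,
    n1_below = below$n1, n2_below = below$n2
  )
}

new_association_curve <- function(tbl, pattern, manifestation, z_threshold = NULL) {
  class(tbl) <- c("association_curve", class(tbl))
  attr(tbl, "pattern") <- pattern
  attr(tbl, "manifestation") <- manifestation
  attr(tbl, "z_threshold") <- z_threshold
  tbl
}

#' Pattern-1 scan: slide an x-axis window at a fixed z threshold
#'
#' For each window start `s` (from the minimum x rounded down to the step
#' grid, advancing by `step` while the window end stays at or below the
#' maximum x), computes the association statistic in the window's
#' half-plane at/above the z threshold and in the one below. Windows where
#' a statistic is undefined carry `NA` with `valid_* = FALSE`, never zero.
#'
#' @inheritParams association_in_region
#' @param z_threshold Fixed z-axis threshold.
#' @param config A [scan_config()].
#' @param manifestation Optional manifestation name stored on the curve.
#' @return An `association_curve` tibble: `position` (window start) plus
#'   statistics, counts and validity flags for both half-planes.
#' @export
scan_pattern1 <- function(embedding, kidney_flags, manifestation_flags,
                          z_threshold, config = scan_config(),
                          manifestation = NULL) {
  x <- embedding$x
  s0 <- snap(config$step * floor(min(x) / config$step + 1e-9))
  starts <- snap(seq(s0, max(x), by = config$step))
  starts <- starts[snap(starts + config$window_width) <= max(x) + 1e-9]
  rows <- purrr::map_dfr(starts, function(s) {
    dplyr::bind_cols(
      tibble::tibble(position = s),
      scan_position(embedding, kidney_flags, manifestation_flags,
                    s, snap(s + config$window_width), z_threshold, config)
    )
  })
  new_association_curve(rows, pattern = 1L, manifestation = manifestation,
                        z_threshold = z_threshold)
}

#' Pattern-2 scan: sweep the z threshold over a fixed x range
#'
#' With x fixed to `config$x_range_pattern2` (half-open), computes the
#' association statistic at/above and below each threshold of a dense
#' sweep: the configured anchor thresholds plus a fine grid (step
#' `config$fine_step`) between their extremes, or an explicit `thresholds`
#' vector.
#'
#' @inheritParams scan_pattern1
#' @param thresholds Optional explicit threshold vector (sorted).
#' @param x_range Optional override of the fixed x interval.
#' @return An `association_curve` tibble with `position` = z threshold.
#' @export
scan_pattern2 <- function(embedding, kidney_flags, manifestation_flags,
                          config = scan_config(), thresholds = NULL,
                          x_range = NULL, manifestation = NULL) {
  x_range <- x_range %||% config$x_range_pattern2
  if (is.null(thresholds)) {
    anchors <- config$z_thresholds
    fine <- seq(min(anchors), max(anchors), by = config$fine_step)
    thresholds <- sort(unique(snap(c(anchors, fine))))
  } else {
    thresholds <- sort(unique(thresholds))
  }
  rows <- purrr::map_dfr(thresholds, function(t) {
    dplyr::bind_cols(
      tibble::tibble(position = t),
      scan_position(embedding, kidney_flags, manifestation_flags,
                    x_range[1], x_range[2], t, config)
    )
  })
  new_association_curve(rows, pattern = 2L, manifestation = manifestation)
}

#' Extract the patient subgroup inside a plane region
#'
#' The published subgroup of interest is the area with x at or above 0.530
#' and z in \[0.490, 0.495).
#'
#' @param embedding `latent_embedding` tibble.
#' @param reg A [region()]; defaults to the published subgroup region.
#' @return Logical mask over the embedding rows, with attribute `n_inside`.
#' @export
extract_subgroup <- function(embedding,
                             reg = region(x_lo = 0.530, z_lo = 0.490, z_hi = 0.495)) {
  mask <- in_region(embedding, reg)
  attr(mask, "n_inside") <- sum(mask)
  mask
}

#' Tidy an association curve
#'
#' @param x An `association_curve`.
#' @param ... Unused.
#' @return Long tibble: `position`, `side` (above/below), `statistic`,
#'   `n1`, `n2`, `valid`, plus the manifestation and pattern.
#' @method tidy association_curve
#' @export
tidy.association_curve <- function(x, ...) {
  long <- dplyr::bind_rows(
    tibble::tibble(position = x$position, side = "above",
                   statistic = x$stat_above, n1 = x$n1_above,
                   n2 = x$n2_above, valid = x$valid_above),
    tibble::tibble(position = x$position, side = "below",
                   statistic = x$stat_below, n1 = x$n1_below,
                   n2 = x$n2_below, valid = x$valid_below)
  )
  long$pattern <- attr(x, "pattern")
  long$manifestation <- attr(x, "manifestation") %||% NA_character_
  long
}
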