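#' Find local maxima of the canopy surface
#'
#' Returns the points that are strictly the highest within their horizontal
#' (x, y) disc of the given radius; exact ties are broken in favor of the
#' lowest point index. These points approximate plant apices when the
#' neighborhood radius is below half the plant spacing.
#'
#' @param cloud a non-empty `point_cloud`
#' @param radius horizontal neighborhood radius in meters (default 0.125)
#' @return a `point_cloud` of local-maximum points
#' @export
find_local_maxima <- function(cloud, radius = 0.125) {
  stopifnot(inherits(cloud, "point_cloud"), radius > 0)
  if (n_points(cloud) == 0) stop("empty cloud")
  m <- cpp_local_maxima(cloud$xyz[, 1], cloud$xyz[, 2], cloud$xyz[, 3],
                        radius)
  subset_cloud(cloud, m)
}

#' Plant heights without known positions (scenario 1)
#'
#' Detects canopy local maxima, pairs each with the lowest point within the
#' same horizontal radius, and takes the height as the difference. Height
#' observations below `min_height` are excluded: they are leaf shoulders or
#' spurious maxima rather than plant apices, given a priori knowledge that
#' all plants exceed that height.
#'
#' @param cloud a `point_cloud` (single frame or combined)
#' @param radius horizontal search radius in meters (default 0.125)
#' @param min_height minimum accepted plant height in meters (default 0.500)
#' @return a data.frame of plant observations: `id`, `x`, `y`, `z_max`,
#'   `z_min`, `height`, `source`
#' @export
heights_scenario1 <- function(cloud, radius = 0.125, min_height = 0.500) {
  mx <- find_local_maxima(cloud, radius)
  mm <- cpp_disc_minmax(cloud$xyz[, 1], cloud$xyz[, 2], cloud$xyz[, 3],
                        mx$xyz[, 1], mx$xyz[, 2], radius)
  h <- mx$xyz[, 3] - mm[, 2]
  keep <- h >= min_height
  data.frame(id = seq_len(sum(keep)),
             x = mx$xyz[keep, 1], y = mx$xyz[keep, 2],
             z_max = mx$xyz[keep, 3], z_min = mm[keep, 2],
             height = h[keep], source = rep("scenario1", sum(keep)),
             row.names = NULL)
}

#' Plant heights at known positions (scenario 2)
#'
#' For every known plant position, extracts the highest and lowest point
#' within the horizontal radius and takes the height as the difference.
#' Positions whose disc contains no points are reported with `NA` values
#' rather than silently dropped.
#'
#' @param cloud a `point_cloud`
#' @param positions data.frame with columns `x`, `y` (and optionally `id`),
#'   or a 2-column matrix
#' @param radius horizontal search radius in meters (default 0.125)
#' @return a data.frame of plant observations: `id`, `x`, `y`, `z_max`,
#'   `z_min`, `height`, `n_points`, `source`
#' @export
heights_scenario2 <- function(cloud, positions, radius = 0.125) {
  stopifnot(inherits(cloud, "point_cloud"))
  if (is.matrix(positions))
    positions <- data.frame(x = positions[, 1], y = positions[, 2])
  stopifnot(nrow(positions) > 0, all(c("x", "y") %in% names(positions)))
  ids <- if ("id" %in% names(positions)) positions$id
         else seq_len(nrow(positions))
  mm <- cpp_disc_minmax(cloud$xyz[, 1], cloud$xyz[, 2], cloud$xyz[, 3],
                        positions$x, positions$y, radius)
  data.frame(id = ids, x = positions$x, y = positions$y,
             z_max = mm[, 1], z_min = mm[, 2],
             height = mm[, 1] - mm[, 2], n_points = as.integer(mm[, 3]),
             source = "scenario2", row.names = NULL)
}

#' Match plant observations to a reference cloud
#'
#' Pairs every test observation with the nearest local maximum of the
#' reference cloud within the horizontal radius, and computes the reference
#' plant height there the same way as in scenario 1 (local maximum minus the
#' lowest point within the radius). Unmatched observations are dropped and
#' counted.
#'
#' @param obs data.frame of observations from [heights_scenario1] or
#'   [heights_scenario2]
#' @param ref_cloud reference `point_cloud` (e.g. a terrestrial laser scan)
#' @param radius horizontal matching radius in meters (default 0.125)
#' @return a list with `pairs` (data.frame: observation columns plus
#'   `ref_height`), `n_unmatched`, and `ref_maxima` (the reference maxima
#'   cloud)
#' @export
match_to_reference <- function(obs, ref_cloud, radius = 0.125) {
  stopifnot(is.data.frame(obs), inherits(ref_cloud, "point_cloud"))
  rm_cloud <- find_local_maxima(ref_cloud, radius)
  ok <- is.finite(obs$height)
  obs_ok <- obs[ok, , drop = FALSE]
  idx <- cpp_nearest_within(obs_ok$x, obs_ok$y,
                            rm_cloud$xyz[, 1], rm_cloud$xyz[, 2], radius)
  matched <- idx > 0
  mm <- cpp_disc_minmax(ref_cloud$xyz[, 1], ref_cloud$xyz[, 2],
                        ref_cloud$xyz[, 3],
                        rm_cloud$xyz[idx[matched], 1],
                        rm_cloud$xyz[idx[matched], 2], radius)
  pairs <- obs_ok[matched, , drop = FALSE]
  pairs$ref_height <- rm_cloud$xyz[idx[matched], 3] - mm[, 2]
  list(pairs = pairs,
       n_unmatched = sum(!matched) + sum(!ok),
       ref_maxima = rm_cloud)
}

#' Compare paired test and reference heights
#'
#' Fits an ordinary least-squares line of test on reference heights and
#' summarizes the paired differences (test - reference) by their median,
#' standard deviation and RMSE.
#'
#' @param test,reference numeric vectors of paired heights in meters
#'   (>= 2 pairs); alternatively `test` may be the list returned by
#'   [match_to_reference], in which case `reference` is ignored
#' @return an object of class `height_comparison`: `n`, `r2`, `slope`,
#'   `intercept`, `median_diff`, `sd_diff`, `rmse_diff`
#' @export
compare_heights <- function(test, reference = NULL) {
  if (is.list(test) && !is.null(test$pairs)) {
    reference <- test$pairs$ref_height
    test <- test$pairs$height
  }
  ok <- is.finite(test) & is.finite(reference)
  test <- test[ok]; reference <- reference[ok]
  if (length(test) < 2) stop("need at least 2 height pairs")
  d <- test - reference
  if (stats::var(reference) > 0 && stats::var(test) > 0) {
    fit <- stats::lm(test ~ reference)
    # a perfect fit is a legitimate outcome here, not a modelling concern
    r2 <- suppressWarnings(summary(fit)$r.squared)
    cf <- stats::coef(fit)
  } else {
    r2 <- if (all(d == d[1])) 1 else NA_real_
    cf <- c(NA_real_, NA_real_)
  }
  structure(list(n = length(test), r2 = r2,
                 slope = unname(cf[2]), intercept = unname(cf[1]),
                 median_diff = stats::median(d), sd_diff = stats::sd(d),
                 rmse_diff = sqrt(mean(d^2))),
            class = "height_comparison")
}

#' @export
print.height_comparison <- function(x, ...) {
  cat(sprintf(paste0("height_comparison: n = %d, R2 = %.3f, slope = %.3f, ",
                     "intercept = %.3f m\n  diff (test - ref): median %.3f, ",
                     "SD %.3f, RMSE %.3f m\n"),
              x$n, x$r2, x$slope, x$intercept,
              x$median_diff, x$sd_diff, x$rmse_diff))
  invisible(x)
}

#' Read / write plant positions and observations as CSV
#'
#' Positions use columns `id, x, y`; observation tables are written with all
#' their columns.
#'
#' @param path CSV path
#' @return `read_positions`: data.frame with `id`, `x`, `y`
#' @export
read_positions <- function(path) {
  d <- utils::read.csv(path)
  if (!all(c("id", "x", "y") %in% names(d)))
    stop("positions CSV must have columns id, x, y")
  d[, c("id", "x", "y")]
}

#' @rdname read_positions
#' @param x data.frame to write
#' @export
write_positions <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}
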