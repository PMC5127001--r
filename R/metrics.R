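#' Normalized median absolute deviation
#'
#' `1.4826 * median(|dh_i - median(dh)|)`: a robust spread estimator that is
#' consistent for the standard deviation under normality and insensitive to
#' blunders below its 50% breakdown point.
#'
#' @param differences non-empty numeric vector (meters)
#' @return NMAD in meters
#' @export
nmad <- function(differences) {
  differences <- differences[!is.na(differences)]
  if (length(differences) == 0) stop("empty difference vector")
  1.4826 * stats::median(abs(differences - stats::median(differences)))
}

# Quantiles use linear interpolation between order statistics (type 7).
q_lin <- function(x, p) unname(stats::quantile(x, p, type = 7, names = FALSE))

#' Robust accuracy report for a difference raster
#'
#' Computes the vertical-accuracy measures recommended for DEM assessment
#' over the valid cells of a difference raster (or a plain numeric vector of
#' differences): RMSE, mean and SD; mean and SD after excluding blunders
#' (differences with `|dh| > blunder_factor * RMSE`); the signed median
#' (`q50`) plus the 68.3% and 95% quantiles of `|dh|`; the NMAD; and a Q-Q
#' normality score (`qq_r2`, the squared Pearson correlation between the
#' sorted standardized differences and standard-normal quantiles; `NA` when
#' the differences are constant).
#'
#' @param diff a `raster_grid` of differences (test - reference) or a
#'   numeric vector
#' @param blunder_factor RMSE multiplier defining blunders (default 3)
#' @return an object of class `accuracy_report` (also a list): `n_cells`,
#'   `rmse`, `mean`, `sd`, `blunder_count`, `mean_no_blunder`,
#'   `sd_no_blunder`, `q50`, `q683`, `q95`, `nmad`, `qq_r2`
#' @export
accuracy_report <- function(diff, blunder_factor = 3) {
  d <- if (inherits(diff, "raster_grid")) as.vector(diff$values) else
    as.numeric(diff)
  d <- d[!is.na(d)]
  if (length(d) < 2) stop("need at least 2 valid difference cells")
  rmse <- sqrt(mean(d^2))
  blunder <- abs(d) > blunder_factor * rmse
  dn <- d[!blunder]
  ad <- abs(d)
  qq_r2 <- NA_real_
  if (stats::sd(d) > 0) {
    zs <- sort((d - mean(d)) / stats::sd(d))
    qn <- stats::qnorm(stats::ppoints(length(d)))
    qq_r2 <- stats::cor(zs, qn)^2
  }
  structure(list(
    n_cells = length(d),
    rmse = rmse,
    mean = mean(d),
    sd = if (length(d) > 1) stats::sd(d) else 0,
    blunder_count = sum(blunder),
    mean_no_blunder = if (length(dn)) mean(dn) else NA_real_,
    sd_no_blunder = if (length(dn) > 1) stats::sd(dn) else 0,
    q50 = stats::median(d),
    q683 = q_lin(ad, 0.683),
    q95 = q_lin(ad, 0.95),
    nmad = nmad(d),
    qq_r2 = qq_r2
  ), class = "accuracy_report")
}

#' @export
print.accuracy_report <- function(x, ...) {
  cat(sprintf(paste0("accuracy_report (n = %d cells)\n",
                     "  RMSE %.4f  mean %.4f  SD %.4f m\n",
                     "  blunders (> %s): %d;  mean/SD without: %.4f / %.4f m\n",
                     "  q50 %.4f  q683(|dh|) %.4f  q95(|dh|) %.4f  NMAD %.4f m\n",
                     "  Q-Q R2: %s\n"),
              x$n_cells, x$rmse, x$mean, x$sd, "3 RMSE", x$blunder_count,
              x$mean_no_blunder, x$sd_no_blunder, x$q50, x$q683, x$q95,
              x$nmad,
              if (is.na(x$qq_r2)) "NA" else sprintf("%.3f", x$qq_r2)))
  invisible(x)
}

#' @export
as.data.frame.accuracy_report <- function(x, ...) {
  data.frame(n_cells = x$n_cells, rmse = x$rmse, mean = x$mean, sd = x$sd,
             blunder_count = x$blunder_count,
             mean_no_blunder = x$mean_no_blunder,
             sd_no_blunder = x$sd_no_blunder,
             q50 = x$q50, q683 = x$q683, q95 = x$q95, nmad = x$nmad,
             qq_r2 = x$qq_r2)
}

#' Cell-level linear fit between two rasters
#'
#' Ordinary least-squares regression of test cell values on reference cell
#' values over the cells valid in both rasters.
#'
#' @param test,reference aligned `raster_grid` objects
#' @return list with `r2`, `slope`, `intercept`, `n`
#' @export
cellwise_fit <- function(test, reference) {
  stopifnot(inherits(test, "raster_grid"), inherits(reference, "raster_grid"))
  if (!grids_aligned(test, reference)) stop("grids are not aligned")
  tv <- as.vector(test$values); rv <- as.vector(reference$values)
  ok <- !is.na(tv) & !is.na(rv)
  if (sum(ok) < 2) stop("need at least 2 co-valid cells")
  tv <- tv[ok]; rv <- rv[ok]
  if (stats::var(rv) == 0) stop("constant reference values: fit undefined")
  fit <- stats::lm(tv ~ rv)
  cf <- stats::coef(fit)
  # exact agreement between rasters is a valid case, silence the perfect-fit
  # note from summary.lm
  list(r2 = suppressWarnings(summary(fit)$r.squared), slope = unname(cf[2]),
       intercept = unname(cf[1]), n = sum(ok))
}

#' Sensor precision and accuracy from a planar-target scan
#'
#' Evaluates a depth-camera scan of a planar target at a known boresight
#' range. Only the central `center_fraction` of the field of view is used
#' (lateral offsets within `center_fraction * z * tan(fov/2)` per axis) to
#' avoid lens-distortion effects at the FOV edges. Precision is the standard
#' deviation of residual distances to a RANSAC-fitted plane; the range error
#' is the difference between the mean measured boresight depth and the
#' nominal range. With a list of repeated scans, the accuracy is aggregated
#' as the RMS of the per-scan range errors.
#'
#' @param cloud a `point_cloud` in the sensor frame (z = boresight depth),
#'   or a list of such clouds (repeated scans)
#' @param nominal_range true target depth in meters
#' @param spec a `frustum_spec` (for the FOV crop)
#' @param center_fraction central FOV fraction to keep (default 1/3)
#' @param dist_threshold,iterations,seed RANSAC parameters, see
#'   [fit_plane_ransac]
#' @return list with `nominal_range`, `precision` (m; mean over repeats),
#'   `accuracy_rmse` (m), `range_errors`, `n_points`
#' @export
plane_precision_accuracy <- function(cloud, nominal_range,
                                     spec = frustum_spec(),
                                     center_fraction = 1 / 3,
                                     dist_threshold = 0.02,
                                     iterations = 200L, seed = 1L) {
  clouds <- if (inherits(cloud, "point_cloud")) list(cloud) else cloud
  stopifnot(length(clouds) >= 1, nominal_range > 0)
  ht <- half_tangents(spec)
  prec <- numeric(length(clouds))
  rerr <- numeric(length(clouds))
  npts <- integer(length(clouds))
  for (i in seq_along(clouds)) {
    xyz <- clouds[[i]]$xyz
    keep <- abs(xyz[, 1]) <= center_fraction * xyz[, 3] * ht["tx"] &
      abs(xyz[, 2]) <= center_fraction * xyz[, 3] * ht["ty"] &
      xyz[, 3] > 0
    xyz <- xyz[keep, , drop = FALSE]
    if (nrow(xyz) < 10) stop("too few points in the central FOV crop")
    pm <- fit_plane_ransac(xyz, dist_threshold = dist_threshold,
                           iterations = iterations, seed = seed + i)
    prec[i] <- stats::sd(pm$residuals[pm$inliers])
    rerr[i] <- mean(xyz[, 3]) - nominal_range
    npts[i] <- nrow(xyz)
  }
  list(nominal_range = nominal_range, precision = mean(prec),
       accuracy_rmse = sqrt(mean(rerr^2)), range_errors = rerr,
       n_points = npts)
}

#' Measurement-artefact statistics over repeated empty-scene frames
#'
#' In a scan of an empty scene every returned point is a measurement
#' artefact. Reports the mean and SD of per-frame artefact counts and the
#' pooled median, maximum and SD of the artefact distances to the frustum
#' boundary (via [frustum_face_distances]); small median distances indicate
#' a concentration of artefacts on the FOV edges.
#'
#' @param frames list of `point_cloud` objects (>= 1), one per repeat
#' @param pose the `sensor_pose` shared by the frames
#' @param spec the `frustum_spec`
#' @return list with `count_mean`, `count_sd`, `dist_median`, `dist_max`,
#'   `dist_sd`, `n_frames`
#' @export
artefact_stats <- function(frames, pose, spec) {
  stopifnot(is.list(frames), length(frames) >= 1)
  counts <- vapply(frames, n_points, integer(1))
  dists <- unlist(lapply(frames, function(f) {
    if (n_points(f) == 0) numeric(0)
    else frustum_face_distances(f, pose, spec)
  }), use.names = FALSE)
  list(count_mean = mean(counts),
       count_sd = if (length(counts) > 1) stats::sd(counts) else 0,
       dist_median = if (length(dists)) stats::median(dists) else NA_real_,
       dist_max = if (length(dists)) max(dists) else NA_real_,
       dist_sd = if (length(dists) > 1) stats::sd(dists) else NA_real_,
       n_frames = length(frames))
}

#' Percentage of points retained by pre-processing
#'
#' @param n_kept,n_original point counts
#' @param digits rounding digits (default 2, the reporting convention)
#' @return percentage of the original cloud retained
#' @export
retention_percent <- function(n_kept, n_original, digits = 2) {
  stopifnot(n_original > 0, n_kept >= 0)
  round(100 * n_kept / n_original, digits)
}

#' Relative height underestimation in percent
#'
#' Expresses a mean height difference as a percentage of a mean crop
#' height, the figure used to judge whether a systematic underestimation is
#' acceptable for an application.
#'
#' @param mean_diff mean height difference in meters (sign ignored)
#' @param mean_height mean crop height in meters (> 0)
#' @param digits rounding digits (default 2)
#' @return percentage
#' @export
relative_underestimation <- function(mean_diff, mean_height, digits = 2) {
  stopifnot(mean_height > 0)
  round(100 * abs(mean_diff) / mean_height, digits)
}
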