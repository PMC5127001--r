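#' Statistical outlier removal
#'
#' For every point the mean Euclidean distance `d_i` to its `k` nearest
#' neighbors is computed (exactly, via a spatial grid index). Points whose
#' `d_i` strictly exceeds `mean(d) + multiplier * sd(d)` are removed as
#' spatially isolated measurement artefacts. With `rule = "sd_only"` the
#' threshold is `sd(d)` alone (an alternative reading of the filter
#' description; it is far more aggressive on densely sampled clouds and is
#' provided only for comparison).
#'
#' @param cloud a `point_cloud` with more than `k` points
#' @param k number of nearest neighbors (default 5)
#' @param multiplier standard-deviation multiplier for the threshold
#' @param rule `"mean_sd"` (default) or `"sd_only"`
#' @return a list with elements `kept` and `removed` (both `point_cloud`),
#'   plus `mean_dist`, `threshold` and `n_removed`
#' @export
sor_filter <- function(cloud, k = 5L, multiplier = 1.0,
                       rule = c("mean_sd", "sd_only")) {
  stopifnot(inherits(cloud, "point_cloud"))
  rule <- match.arg(rule)
  n <- n_points(cloud)
  if (n <= k) stop("cloud must have more than k points")
  d <- cpp_knn_mean_dist(cloud$xyz, as.integer(k))
  thr <- switch(rule,
                mean_sd = mean(d) + multiplier * stats::sd(d),
                sd_only = stats::sd(d))
  out <- d > thr
  list(kept = subset_cloud(cloud, !out),
       removed = subset_cloud(cloud, out),
       mean_dist = d, threshold = thr, n_removed = sum(out))
}

#' Least-squares rigid registration from tie points
#'
#' Closed-form solution (SVD / Kabsch) of the rotation and translation
#' minimizing the sum of squared distances between transformed source points
#' and their target counterparts. No scale is estimated. The report carries
#' the per-pair residual 3D distances and their standard deviation, the
#' figure used to judge registration quality in the field.
#'
#' @param source `n x 3` matrix of source tie-point coordinates (n >= 3,
#'   non-collinear)
#' @param target `n x 3` matrix of corresponding target coordinates
#' @return an object of class `registration_report` with elements
#'   `transform` (a [rigid_transform]), `residuals` (per-pair 3D distances,
#'   meters), `residual_sd` and `rmse`
#' @export
rigid_from_tiepoints <- function(source, target) {
  source <- as.matrix(source); target <- as.matrix(target)
  if (!all(dim(source) == dim(target)) || ncol(source) != 3)
    stop("source and target must be matching n x 3 matrices")
  n <- nrow(source)
  if (n < 3) stop("need at least 3 tie-point pairs")
  if (anyDuplicated(source)) stop("duplicated source tie points")
  cs <- colMeans(source); ct <- colMeans(target)
  A <- sweep(source, 2, cs); B <- sweep(target, 2, ct)
  H <- crossprod(A, B)
  sv <- svd(H)
  if (sv$d[2] < 1e-12 * max(sv$d[1], 1e-300))
    stop("degenerate (collinear) tie-point configuration")
  S <- diag(c(1, 1, sign(det(sv$v %*% t(sv$u)))))
  R <- sv$v %*% S %*% t(sv$u)
  t <- ct - as.vector(R %*% cs)
  tr <- rigid_transform(R, t)
  res <- sqrt(rowSums((apply_transform(tr, source) - target)^2))
  structure(list(transform = tr, residuals = res,
                 residual_sd = stats::sd(res),
                 rmse = sqrt(mean(res^2)), n_pairs = n),
            class = "registration_report")
}

#' @export
print.registration_report <- function(x, ...) {
  cat(sprintf("registration_report: %d tie-point pairs, residual SD %.5f m, RMSE %.5f m\n",
              x$n_pairs, x$residual_sd, x$rmse))
  invisible(x)
}

#' Read tie points from CSV
#'
#' Expects a header and six columns `xs, ys, zs, xt, yt, zt`: source
#' coordinates followed by target coordinates, meters.
#'
#' @param path CSV file path
#' @return list with matrices `source` and `target`
#' @export
read_tiepoints <- function(path) {
  d <- utils::read.csv(path)
  need <- c("xs", "ys", "zs", "xt", "yt", "zt")
  if (!all(need %in% names(d)))
    stop("tie-point CSV must have columns: ", paste(need, collapse = ", "))
  list(source = as.matrix(d[, c("xs", "ys", "zs")]),
       target = as.matrix(d[, c("xt", "yt", "zt")]))
}

#' Standard pre-processing chain for a depth-camera frame
#'
#' Applies, in order: clipping to the FOV cross-section at the canopy top,
#' cropping to the area of interest, and statistical outlier removal. The
#' returned retention summary mirrors the bookkeeping used to report how
#' many raw sensor points survive pre-processing.
#'
#' @param cloud raw frame (`point_cloud`, world frame)
#' @param pose the frame's `sensor_pose`
#' @param spec the sensor `frustum_spec`
#' @param top_range boresight depth of the canopy top (meters)
#' @param aoi numeric vector `c(xmin, ymin, xmax, ymax)`
#' @param sor_k,sor_multiplier outlier-filter parameters (see [sor_filter])
#' @return list with `cloud` (the cleaned `point_cloud`) and `retention`, a
#'   one-row data.frame with point counts after each stage and the percent
#'   of the original cloud retained
#' @export
preprocess_frame <- function(cloud, pose, spec, top_range, aoi,
                             sor_k = 5L, sor_multiplier = 1.0) {
  n0 <- n_points(cloud)
  clipped <- clip_to_top_fov(cloud, pose, spec, top_range)
  cropped <- crop_to_aoi(clipped, aoi[1], aoi[2], aoi[3], aoi[4])
  if (n_points(cropped) > sor_k) {
    filt <- sor_filter(cropped, k = sor_k, multiplier = sor_multiplier)
    final <- filt$kept
  } else {
    final <- cropped
  }
  list(cloud = final,
       retention = data.frame(
         n_original = n0, n_fov = n_points(clipped),
         n_aoi = n_points(cropped), n_final = n_points(final),
         pct_retained = retention_percent(n_points(final), n0)))
}
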