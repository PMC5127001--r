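#' Point cloud container
#'
#' A `point_cloud` stores XYZ coordinates in meters as an `n x 3` numeric
#' matrix plus optional per-point attributes (e.g. a source pose id). It is
#' the universal currency of the processing chain: every clipping, filtering,
#' rasterization and plant-extraction step consumes and/or produces one.
#'
#' @param xyz numeric matrix with 3 columns (x, y, z in meters), or a
#'   data.frame with columns `x`, `y`, `z`.
#' @param ... named per-point attribute vectors; each must have one entry
#'   per point.
#' @return an object of class `point_cloud` with elements `xyz` (matrix)
#'   and `attrs` (named list of vectors, possibly empty).
#' @examples
#' pc <- point_cloud(cbind(runif(10), runif(10), runif(10)))
#' n_points(pc)
#' @export
point_cloud <- function(xyz, ...) {
  if (is.data.frame(xyz)) {
    stopifnot(all(c("x", "y", "z") %in% names(xyz)))
    xyz <- as.matrix(xyz[, c("x", "y", "z")])
  }
  xyz <- matrix(as.numeric(xyz), ncol = 3,
                dimnames = list(NULL, c("x", "y", "z")))
  if (any(!is.finite(xyz))) stop("point coordinates must be finite")
  attrs <- list(...)
  n <- nrow(xyz)
  for (nm in names(attrs)) {
    if (length(attrs[[nm]]) != n)
      stop("attribute '", nm, "' length does not match point count")
  }
  structure(list(xyz = xyz, attrs = attrs), class = "point_cloud")
}

#' Number of points in a cloud
#' @param cloud a `point_cloud`
#' @return integer point count
#' @export
n_points <- function(cloud) {
  stopifnot(inherits(cloud, "point_cloud"))
  nrow(cloud$xyz)
}

#' Subset a point cloud by index or logical mask
#'
#' Attributes are subset consistently.
#'
#' @param cloud a `point_cloud`
#' @param idx integer indices or logical mask
#' @return a `point_cloud`
#' @export
subset_cloud <- function(cloud, idx) {
  stopifnot(inherits(cloud, "point_cloud"))
  xyz <- cloud$xyz[idx, , drop = FALSE]
  out <- point_cloud(xyz)
  out$attrs <- lapply(cloud$attrs, function(a) a[idx])
  out
}

#' @export
print.point_cloud <- function(x, ...) {
  cat("point_cloud:", nrow(x$xyz), "points")
  if (length(x$attrs))
    cat(" | attributes:", paste(names(x$attrs), collapse = ", "))
  cat("\n")
  if (nrow(x$xyz) > 0) {
    r <- apply(x$xyz, 2, range)
    cat(sprintf("  x: [%.3f, %.3f]  y: [%.3f, %.3f]  z: [%.3f, %.3f] m\n",
                r[1, 1], r[2, 1], r[1, 2], r[2, 2], r[1, 3], r[2, 3]))
  }
  invisible(x)
}

#' @export
as.data.frame.point_cloud <- function(x, ...) {
  d <- as.data.frame(x$xyz)
  for (nm in names(x$attrs)) d[[nm]] <- x$attrs[[nm]]
  d
}

#' Merge point clouds into one, tagging point origin
#'
#' Concatenates clouds expressed in a common coordinate frame. A `source`
#' attribute records, for every point, which input cloud it came from; if an
#' input already carries a `source` attribute it is preserved.
#'
#' @param clouds list of `point_cloud` objects (all in one frame)
#' @param ids optional vector of source ids (defaults to list names or
#'   1..n)
#' @return a `point_cloud` with a `source` attribute
#' @export
merge_clouds <- function(clouds, ids = NULL) {
  if (!is.list(clouds) || length(clouds) == 0)
    stop("need a non-empty list of point clouds")
  if (inherits(clouds, "point_cloud")) clouds <- list(clouds)
  stopifnot(all(vapply(clouds, inherits, logical(1), "point_cloud")))
  if (is.null(ids)) {
    ids <- names(clouds)
    if (is.null(ids)) ids <- as.character(seq_along(clouds))
  }
  xyz <- do.call(rbind, lapply(clouds, `[[`, "xyz"))
  src <- unlist(lapply(seq_along(clouds), function(i) {
    a <- clouds[[i]]$attrs$source
    if (is.null(a)) rep(ids[[i]], nrow(clouds[[i]]$xyz)) else a
  }), use.names = FALSE)
  point_cloud(xyz, source = src)
}

#' Crop a cloud to a rectangular area of interest
#'
#' Keeps points with `xmin <= x <= xmax` and `ymin <= y <= ymax` (closed
#' box; boundary points are retained). Used to clip field data to the plot
#' extent before rasterization.
#'
#' @param cloud a `point_cloud`
#' @param xmin,ymin,xmax,ymax AOI bounds in meters
#' @return the cropped `point_cloud`
#' @export
crop_to_aoi <- function(cloud, xmin, ymin, xmax, ymax) {
  stopifnot(inherits(cloud, "point_cloud"))
  if (!(xmin < xmax) || !(ymin < ymax))
    stop("inverted AOI bounds: require xmin < xmax and ymin < ymax")
  keep <- cloud$xyz[, 1] >= xmin & cloud$xyz[, 1] <= xmax &
    cloud$xyz[, 2] >= ymin & cloud$xyz[, 2] <= ymax
  subset_cloud(cloud, keep)
}
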