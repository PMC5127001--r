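#' Sensor frustum specification
#'
#' Field-of-view geometry of a time-of-flight depth camera: full horizontal
#' and vertical opening angles, pixel grid dimensions and the usable depth
#' range. The default corresponds to a consumer TOF camera with a 70 x 60
#' degree FOV, 512 x 424 pixels and a working range of 0.5-4.5 m, i.e.
#' 217,088 range measurements per frame.
#'
#' Depth here is measured along the boresight axis (sensor-frame z), so the
#' frustum is a flat-capped pyramid: a point is inside iff
#' `min_range <= z <= max_range`, `|x| <= z tan(h_fov/2)` and
#' `|y| <= z tan(v_fov/2)` in the sensor frame.
#'
#' @param h_fov,v_fov full opening angles in degrees (0, 180)
#' @param n_cols,n_rows pixel grid dimensions
#' @param min_range,max_range usable boresight depth limits in meters
#' @return an object of class `frustum_spec`
#' @export
frustum_spec <- function(h_fov = 70, v_fov = 60, n_cols = 512L,
                         n_rows = 424L, min_range = 0.5, max_range = 4.5) {
  if (!(h_fov > 0 && h_fov < 180 && v_fov > 0 && v_fov < 180))
    stop("FOV angles must be in (0, 180) degrees")
  if (n_cols < 1 || n_rows < 1) stop("pixel counts must be >= 1")
  if (!(min_range > 0 && min_range < max_range))
    stop("require 0 < min_range < max_range")
  structure(list(h_fov = h_fov, v_fov = v_fov,
                 n_cols = as.integer(n_cols), n_rows = as.integer(n_rows),
                 min_range = min_range, max_range = max_range),
            class = "frustum_spec")
}

#' @export
print.frustum_spec <- function(x, ...) {
  cat(sprintf("frustum_spec: %g x %g deg FOV, %d x %d px (%d rays), range [%g, %g] m\n",
              x$h_fov, x$v_fov, x$n_cols, x$n_rows, x$n_cols * x$n_rows,
              x$min_range, x$max_range))
  invisible(x)
}

#' Total pixel (ray) count of a frustum spec
#' @param spec a `frustum_spec`
#' @return integer number of range measurements per frame
#' @export
n_pixels <- function(spec) {
  stopifnot(inherits(spec, "frustum_spec"))
  spec$n_cols * spec$n_rows
}

deg2rad <- function(d) d * pi / 180

half_tangents <- function(spec) {
  c(tx = tan(deg2rad(spec$h_fov) / 2), ty = tan(deg2rad(spec$v_fov) / 2))
}

#' Theoretical point spacing of an angular sensor
#'
#' Spacing between adjacent range measurements at a given range, computed
#' from the full opening angle and the number of measurements across it:
#' `2 * range * tan(full_angle / 2) / n_pixels`. With `n_pixels = 1` this is
#' the footprint of a single angular step, which is how the point spacing of
#' a laser scanner with a given angular resolution is obtained.
#'
#' @param range scanning range in meters (> 0)
#' @param full_angle full opening angle in degrees, in (0, 180)
#' @param n_pixels number of measurements across the angle (>= 1)
#' @return spacing in meters
#' @examples
#' theoretical_spacing(0.5, 70, 512)   # ~0.0014 m
#' theoretical_spacing(4.0, 70, 512)   # ~0.0109 m
#' theoretical_spacing(5, 0.029, 1)    # ~0.0025 m
#' @export
theoretical_spacing <- function(range, full_angle, n_pixels) {
  if (any(range <= 0)) stop("range must be positive")
  if (any(full_angle <= 0 | full_angle >= 180))
    stop("full_angle must be in (0, 180) degrees")
  if (any(n_pixels < 1)) stop("n_pixels must be >= 1")
  2 * range * tan(deg2rad(full_angle) / 2) / n_pixels
}

#' Rigid transform (rotation + translation)
#'
#' @param rotation 3x3 orthonormal matrix with determinant +1
#' @param translation length-3 numeric vector (meters)
#' @return an object of class `rigid_transform`
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- matrix(as.numeric(rotation), 3, 3)
  translation <- as.numeric(translation)
  stopifnot(length(translation) == 3)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-6 ||
      abs(det(rotation) - 1) > 1e-6)
    stop("rotation must be orthonormal with determinant +1")
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat("rigid_transform\n  rotation:\n")
  print(round(x$rotation, 6))
  cat("  translation:", paste(sprintf("%.6f", x$translation), collapse = " "),
      "\n")
  invisible(x)
}

#' Apply a rigid transform to coordinates or a point cloud
#' @param transform a `rigid_transform`
#' @param x an `n x 3` matrix or a `point_cloud`
#' @return object of the same kind with transformed coordinates
#' @export
apply_transform <- function(transform, x) {
  stopifnot(inherits(transform, "rigid_transform"))
  if (inherits(x, "point_cloud")) {
    out <- x
    out$xyz <- apply_transform(transform, x$xyz)
    return(out)
  }
  sweep(x %*% t(transform$rotation), 2, transform$translation, `+`)
}

#' Compose two rigid transforms (`a` applied after `b`)
#' @param a,b `rigid_transform` objects
#' @return the composed `rigid_transform`
#' @export
compose_transforms <- function(a, b) {
  rigid_transform(a$rotation %*% b$rotation,
                  as.vector(a$rotation %*% b$translation) + a$translation)
}

#' Invert a rigid transform
#' @param transform a `rigid_transform`
#' @return the inverse `rigid_transform`
#' @export
invert_transform <- function(transform) {
  rt <- t(transform$rotation)
  rigid_transform(rt, -as.vector(rt %*% transform$translation))
}

#' Sensor pose in the world frame
#'
#' `rotation` maps sensor-frame coordinates to world-frame directions; the
#' sensor frame has z along the boresight, x across columns and y across
#' rows. The world frame is Z-up.
#'
#' @param origin sensor position, length-3 (meters, world frame)
#' @param rotation 3x3 orthonormal matrix, sensor frame to world frame
#' @return an object of class `sensor_pose`
#' @export
sensor_pose <- function(origin, rotation) {
  rt <- rigid_transform(rotation, origin)
  structure(list(origin = as.numeric(origin), rotation = rt$rotation),
            class = "sensor_pose")
}

#' Nadir sensor pose
#'
#' Pose of a sensor looking straight down (boresight along world -Z) from a
#' given position, with the sensor x axis rotated by `yaw` degrees from
#' world +X. This is the mounting used for crop scanning from above, which
#' minimizes terrain occlusion by the plants.
#'
#' @param x,y,z sensor position in meters (world frame, Z-up)
#' @param yaw rotation of the sensor x axis about world Z, degrees
#' @return a `sensor_pose`
#' @export
nadir_pose <- function(x, y, z, yaw = 0) {
  a <- deg2rad(yaw)
  rz <- matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
  # sensor x -> world x, sensor y -> world -y, sensor z -> world -z
  flip <- diag(c(1, -1, -1))
  sensor_pose(c(x, y, z), rz %*% flip)
}

#' Express world coordinates in the sensor frame
#' @param xyz `n x 3` matrix of world coordinates
#' @param pose a `sensor_pose`
#' @return `n x 3` matrix of sensor-frame coordinates
#' @export
to_sensor_frame <- function(xyz, pose) {
  stopifnot(inherits(pose, "sensor_pose"))
  sweep(xyz, 2, pose$origin, `-`) %*% pose$rotation
}

#' Express sensor-frame coordinates in the world frame
#' @param xyz `n x 3` matrix of sensor-frame coordinates
#' @param pose a `sensor_pose`
#' @return `n x 3` matrix of world coordinates
#' @export
to_world_frame <- function(xyz, pose) {
  stopifnot(inherits(pose, "sensor_pose"))
  sweep(xyz %*% t(pose$rotation), 2, pose$origin, `+`)
}

#' Test whether points lie inside the sensor frustum
#'
#' A point is inside iff, in the sensor frame, its boresight depth z lies in
#' `[min_range, max_range]` and its lateral offsets satisfy
#' `|x| <= z tan(h_fov/2)` and `|y| <= z tan(v_fov/2)` (closed boundaries).
#'
#' @param xyz `n x 3` matrix of world coordinates, or a `point_cloud`
#' @param pose a `sensor_pose`
#' @param spec a `frustum_spec`
#' @return logical vector, one entry per point
#' @export
frustum_contains <- function(xyz, pose, spec) {
  if (inherits(xyz, "point_cloud")) xyz <- xyz$xyz
  stopifnot(inherits(spec, "frustum_spec"))
  s <- to_sensor_frame(xyz, pose)
  ht <- half_tangents(spec)
  z <- s[, 3]
  z >= spec$min_range & z <= spec$max_range &
    abs(s[, 1]) <= z * ht["tx"] & abs(s[, 2]) <= z * ht["ty"]
}

#' Clip a cloud to the FOV cross-section at the canopy top
#'
#' Keeps only points whose sensor-frame lateral coordinates fall within the
#' FOV rectangle evaluated at `top_range` - the frustum cross-section at the
#' depth of the highest plant in the scene. Points near the splayed lower
#' FOV margin and the FOV-edge artefact band are removed, because at their
#' depth they lie laterally outside this rectangle. Boundary points are
#' retained (closed rectangle) so canopy-top points on an edge are never
#' silently dropped.
#'
#' @param cloud a `point_cloud` (world frame)
#' @param pose a `sensor_pose`
#' @param spec a `frustum_spec`
#' @param top_range boresight depth of the canopy top in meters; must lie in
#'   `[min_range, max_range]`
#' @return the clipped `point_cloud`
#' @export
clip_to_top_fov <- function(cloud, pose, spec, top_range) {
  stopifnot(inherits(cloud, "point_cloud"), inherits(spec, "frustum_spec"))
  if (top_range < spec$min_range || top_range > spec$max_range)
    stop("top_range must lie within [min_range, max_range]")
  s <- to_sensor_frame(cloud$xyz, pose)
  ht <- half_tangents(spec)
  keep <- abs(s[, 1]) <= top_range * ht["tx"] &
    abs(s[, 2]) <= top_range * ht["ty"]
  subset_cloud(cloud, keep)
}

# Evaluate an expression with a private, restored RNG state.
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

# Least-squares (total) plane through points: returns unit normal and offset
# such that dot(normal, p) = offset for points on the plane.
fit_plane_lsq <- function(xyz) {
  ctr <- colMeans(xyz)
  cc <- crossprod(sweep(xyz, 2, ctr))
  ev <- eigen(cc, symmetric = TRUE)
  normal <- ev$vectors[, 3]
  if (ev$values[2] < 1e-12 * max(ev$values[1], 1e-300))
    stop("degenerate (collinear) point configuration")
  if (normal[3] < 0) normal <- -normal
  list(normal = normal, offset = sum(normal * ctr))
}

#' Robust plane fit by random sample consensus
#'
#' Repeatedly draws 3-point samples, counts points within `dist_threshold`
#' of the candidate plane, keeps the consensus set of the best candidate and
#' refines it by a total-least-squares fit on the inliers (the inlier mask
#' is then recomputed against the refined plane). Deterministic for a given
#' `seed`. Used to characterize sensor precision from scans of a planar
#' target.
#'
#' @param cloud a `point_cloud` or `n x 3` matrix (n >= 3, non-collinear)
#' @param dist_threshold inlier distance threshold in meters
#' @param iterations number of random samples
#' @param seed integer seed making the fit reproducible
#' @return an object of class `plane_model`: unit `normal` (`normal[3] >= 0`),
#'   scalar `offset` (signed distance of the origin: plane is
#'   `dot(normal, p) = offset`), logical `inliers`, numeric `residuals`
#'   (signed point-plane distances).
#' @export
fit_plane_ransac <- function(cloud, dist_threshold = 0.01, iterations = 500L,
                             seed = 1L) {
  xyz <- if (inherits(cloud, "point_cloud")) cloud$xyz else cloud
  n <- nrow(xyz)
  if (n < 3) stop("need at least 3 points")
  best_count <- -1L
  best_normal <- NULL
  best_offset <- NULL
  with_seed(seed, {
    for (it in seq_len(iterations)) {
      idx <- sample.int(n, 3)
      a <- xyz[idx[1], ]; b <- xyz[idx[2], ]; c <- xyz[idx[3], ]
      nv <- c((b - a)[2] * (c - a)[3] - (b - a)[3] * (c - a)[2],
              (b - a)[3] * (c - a)[1] - (b - a)[1] * (c - a)[3],
              (b - a)[1] * (c - a)[2] - (b - a)[2] * (c - a)[1])
      nn <- sqrt(sum(nv^2))
      if (nn < 1e-12) next
      nv <- nv / nn
      off <- sum(nv * a)
      cnt <- sum(abs(xyz %*% nv - off) <= dist_threshold)
      if (cnt > best_count) {
        best_count <- cnt
        best_normal <- nv
        best_offset <- off
      }
    }
  })
  if (is.null(best_normal))
    stop("degenerate (collinear) point configuration")
  inl <- abs(xyz %*% best_normal - best_offset) <= dist_threshold
  refined <- fit_plane_lsq(xyz[inl, , drop = FALSE])
  res <- as.vector(xyz %*% refined$normal - refined$offset)
  inliers <- abs(res) <= dist_threshold
  structure(list(normal = refined$normal, offset = refined$offset,
                 inliers = inliers, residuals = res,
                 n_inliers = sum(inliers)),
            class = "plane_model")
}

#' @export
print.plane_model <- function(x, ...) {
  cat(sprintf("plane_model: normal (%.4f, %.4f, %.4f), offset %.4f m, %d/%d inliers\n",
              x$normal[1], x$normal[2], x$normal[3], x$offset,
              x$n_inliers, length(x$inliers)))
  invisible(x)
}

# Frustum boundary mesh: 12 triangles covering the 4 side faces and the
# near/far caps, in world coordinates.
frustum_mesh <- function(pose, spec) {
  ht <- half_tangents(spec)
  corners_at <- function(d)
    rbind(c(-d * ht[1], -d * ht[2], d), c(d * ht[1], -d * ht[2], d),
          c(d * ht[1], d * ht[2], d), c(-d * ht[1], d * ht[2], d))
  cn <- corners_at(spec$min_range)  # near cap corners 1..4
  cf <- corners_at(spec$max_range)  # far cap corners 5..8
  v <- to_world_frame(rbind(cn, cf), pose)
  quads <- rbind(c(1, 2, 3, 4),          # near cap
                 c(5, 6, 7, 8),          # far cap
                 c(1, 2, 6, 5),          # bottom side (y = -)
                 c(2, 3, 7, 6),          # right side (x = +)
                 c(3, 4, 8, 7),          # top side (y = +)
                 c(4, 1, 5, 8))          # left side (x = -)
  tri <- do.call(rbind, lapply(seq_len(nrow(quads)), function(i) {
    q <- quads[i, ]
    rbind(q[c(1, 2, 3)], q[c(1, 3, 4)])
  }))
  list(vertices = v, triangles = tri)
}

# Exact minimum distances from points P (n x 3) to triangle (a, b, c),
# vectorized over points (Eberly's region decomposition).
point_triangle_distance <- function(P, a, b, c) {
  E0 <- b - a
  E1 <- c - a
  D <- sweep(P, 2, a, `-`)
  a00 <- sum(E0 * E0); a01 <- sum(E0 * E1); a11 <- sum(E1 * E1)
  b0 <- -(D %*% E0); b1 <- -(D %*% E1)
  det <- a00 * a11 - a01 * a01
  s <- a01 * b1 - a11 * b0
  t <- a01 * b0 - a00 * b1
  n <- nrow(P)
  s_out <- numeric(n); t_out <- numeric(n)
  for (i in seq_len(n)) {
    si <- s[i]; ti <- t[i]
    if (si + ti <= det) {
      if (si < 0) {
        if (ti < 0) { # region 4
          if (b0[i] < 0) { ti <- 0; si <- min(max(-b0[i] / a00, 0), 1) }
          else { si <- 0; ti <- min(max(-b1[i] / a11, 0), 1) }
        } else {      # region 3
          si <- 0; ti <- min(max(-b1[i] / a11, 0), 1)
        }
      } else if (ti < 0) { # region 5
        ti <- 0; si <- min(max(-b0[i] / a00, 0), 1)
      } else {             # region 0
        si <- si / det; ti <- ti / det
      }
    } else {
      if (si < 0) {        # region 2
        tmp0 <- a01 + b0[i]; tmp1 <- a11 + b1[i]
        if (tmp1 > tmp0) {
          numer <- tmp1 - tmp0
          denom <- a00 - 2 * a01 + a11
          si <- min(max(numer / denom, 0), 1); ti <- 1 - si
        } else {
          si <- 0; ti <- min(max(-b1[i] / a11, 0), 1)
        }
      } else if (ti < 0) { # region 6
        tmp0 <- a01 + b1[i]; tmp1 <- a00 + b0[i]
        if (tmp1 > tmp0) {
          numer <- tmp1 - tmp0
          denom <- a00 - 2 * a01 + a11
          ti <- min(max(numer / denom, 0), 1); si <- 1 - ti
        } else {
          ti <- 0; si <- min(max(-b0[i] / a00, 0), 1)
        }
      } else {             # region 1
        numer <- a11 + b1[i] - a01 - b0[i]
        denom <- a00 - 2 * a01 + a11
        si <- min(max(numer / denom, 0), 1); ti <- 1 - si
      }
    }
    s_out[i] <- si; t_out[i] <- ti
  }
  closest <- sweep(outer(s_out, E0) + outer(t_out, E1), 2, a, `+`)
  sqrt(rowSums((P - closest)^2))
}

#' Distance of points to the frustum boundary surface
#'
#' Shortest Euclidean distance from each point to the frustum boundary mesh
#' (the four side faces plus the near and far caps, triangulated). Used to
#' characterize the spatial distribution of measurement artefacts, which
#' concentrate on the FOV edges.
#'
#' @param cloud a `point_cloud` or `n x 3` matrix (world frame)
#' @param pose a `sensor_pose`
#' @param spec a `frustum_spec`
#' @return numeric vector of distances in meters, one per point
#' @export
frustum_face_distances <- function(cloud, pose, spec) {
  xyz <- if (inherits(cloud, "point_cloud")) cloud$xyz else cloud
  if (nrow(xyz) == 0) return(numeric(0))
  mesh <- frustum_mesh(pose, spec)
  d <- rep(Inf, nrow(xyz))
  for (i in seq_len(nrow(mesh$triangles))) {
    tr <- mesh$triangles[i, ]
    di <- point_triangle_distance(xyz, mesh$vertices[tr[1], ],
                                  mesh$vertices[tr[2], ],
                                  mesh$vertices[tr[3], ])
    d <- pmin(d, di)
  }
  d
}
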