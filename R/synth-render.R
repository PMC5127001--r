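#' Range noise model of a virtual depth sensor
#'
#' Range-dependent noise applied along the measurement ray: a Gaussian
#' component with standard deviation `sd(range)` (the sensor's precision)
#' and a systematic component `bias(range)` (its accuracy). Both are linear
#' between anchor points and held constant outside them. The defaults anchor
#' the precision at 0.001 m @ 0.8 m to 0.003 m @ 4.0 m and the bias
#' magnitude at 0.005 m @ 0.8 m to 0.024 m @ 4.0 m, with a negative sign
#' (ranges underestimated, increasingly so with distance).
#'
#' @param sd_ranges,sd_values anchor ranges (m) and noise SDs (m)
#' @param bias_ranges,bias_values anchor ranges (m) and signed biases (m)
#' @return an object of class `noise_model`
#' @export
noise_model <- function(sd_ranges = c(0.8, 4.0),
                        sd_values = c(0.001, 0.003),
                        bias_ranges = c(0.8, 4.0),
                        bias_values = c(-0.005, -0.024)) {
  stopifnot(length(sd_ranges) == length(sd_values),
            length(bias_ranges) == length(bias_values),
            all(sd_values >= 0))
  structure(list(sd_ranges = sd_ranges, sd_values = sd_values,
                 bias_ranges = bias_ranges, bias_values = bias_values),
            class = "noise_model")
}

#' Noise-free sensor model
#' @return a `noise_model` with zero SD and zero bias
#' @export
noise_none <- function() {
  noise_model(sd_values = c(0, 0), bias_values = c(0, 0))
}

#' Evaluate the noise SD / bias of a noise model at given ranges
#' @param model a `noise_model`
#' @param range ranges in meters
#' @return numeric vector of SDs (`noise_sd`) or signed biases
#'   (`noise_bias`) in meters
#' @export
noise_sd <- function(model, range) {
  if (length(unique(model$sd_values)) == 1) {
    rep(model$sd_values[1], length(range))
  } else {
    stats::approx(model$sd_ranges, model$sd_values, range, rule = 2)$y
  }
}

#' @rdname noise_sd
#' @export
noise_bias <- function(model, range) {
  if (length(unique(model$bias_values)) == 1) {
    rep(model$bias_values[1], length(range))
  } else {
    stats::approx(model$bias_ranges, model$bias_values, range, rule = 2)$y
  }
}

#' Measurement-artefact model for a virtual depth sensor
#'
#' Spurious 3D points reported in empty space. Per frame, the artefact count
#' is drawn from a normal distribution (truncated at zero and rounded) whose
#' mean/SD defaults depend on the lighting condition: night 50 (7.4),
#' diffuse 195 (14.4), direct sun facing away 202 (10.1), facing into the
#' sun 218 (13.4). A fraction `face_fraction` of artefacts is placed within
#' `face_offset` of the frustum boundary faces (artefacts concentrate on the
#' FOV edges); the rest is uniform in the frustum volume. In `"into_sun"`
#' mode an additional column of artefacts appears along a sun direction
#' inside the FOV (its geometry is a free parameter of the model).
#'
#' @param lighting one of `"night"`, `"diffuse"`, `"away"`, `"into_sun"`
#' @param count_mean,count_sd override the per-lighting count distribution
#' @param face_fraction fraction of artefacts near the FOV faces
#' @param face_offset max distance from a face for "near-face" artefacts (m)
#' @param column_fraction fraction placed along the sun column
#'   (`"into_sun"` only)
#' @return an object of class `artefact_model`
#' @export
artefact_model <- function(lighting = c("night", "diffuse", "away",
                                        "into_sun"),
                           count_mean = NULL, count_sd = NULL,
                           face_fraction = 0.85, face_offset = 0.02,
                           column_fraction = 0.10) {
  lighting <- match.arg(lighting)
  defaults <- list(night = c(50, 7.4), diffuse = c(195, 14.4),
                   away = c(202, 10.1), into_sun = c(218, 13.4))
  d <- defaults[[lighting]]
  structure(list(lighting = lighting,
                 count_mean = if (is.null(count_mean)) d[1] else count_mean,
                 count_sd = if (is.null(count_sd)) d[2] else count_sd,
                 face_fraction = face_fraction, face_offset = face_offset,
                 column_fraction = if (lighting == "into_sun")
                   column_fraction else 0),
            class = "artefact_model")
}

# Draw artefact points in the sensor frame. Returns an m x 3 matrix.
draw_artefacts <- function(model, spec) {
  m <- max(0L, round(stats::rnorm(1, model$count_mean, model$count_sd)))
  if (m == 0) return(matrix(numeric(0), 0, 3))
  ht <- half_tangents(spec)
  n_col <- round(m * model$column_fraction)
  n_face <- round((m - n_col) * model$face_fraction)
  n_vol <- m - n_col - n_face
  pts <- list()
  if (n_face > 0) {
    # pick a face (4 sides + 2 caps) by area weight, a point on it, then
    # offset inward by up to face_offset
    z <- stats::runif(n_face, spec$min_range, spec$max_range)
    face <- sample.int(6, n_face, replace = TRUE,
                       prob = c(ht[1], ht[1], ht[2], ht[2], 0.25, 0.25))
    x <- stats::runif(n_face, -1, 1) * z * ht[1]
    y <- stats::runif(n_face, -1, 1) * z * ht[2]
    off <- stats::runif(n_face, 0, model$face_offset)
    px <- x; py <- y; pz <- z
    sel <- face == 1; px[sel] <- (pz[sel] * ht[1] - off[sel])
    sel <- face == 2; px[sel] <- -(pz[sel] * ht[1] - off[sel])
    sel <- face == 3; py[sel] <- (pz[sel] * ht[2] - off[sel])
    sel <- face == 4; py[sel] <- -(pz[sel] * ht[2] - off[sel])
    sel <- face == 5
    pz[sel] <- spec$min_range + off[sel]
    px[sel] <- stats::runif(sum(sel), -1, 1) * pz[sel] * ht[1]
    py[sel] <- stats::runif(sum(sel), -1, 1) * pz[sel] * ht[2]
    sel <- face == 6
    pz[sel] <- spec$max_range - off[sel]
    px[sel] <- stats::runif(sum(sel), -1, 1) * pz[sel] * ht[1]
    py[sel] <- stats::runif(sum(sel), -1, 1) * pz[sel] * ht[2]
    pts[[length(pts) + 1]] <- cbind(px, py, pz)
  }
  if (n_vol > 0) {
    z <- stats::runif(n_vol, spec$min_range, spec$max_range)
    pts[[length(pts) + 1]] <- cbind(stats::runif(n_vol, -1, 1) * z * ht[1],
                                    stats::runif(n_vol, -1, 1) * z * ht[2],
                                    z)
  }
  if (n_col > 0) {
    # a loose column of points along a fixed oblique direction in the FOV
    t <- stats::runif(n_col, spec$min_range, spec$max_range)
    dir <- c(0.3 * ht[1], 0.3 * ht[2], 1)
    pts[[length(pts) + 1]] <-
      cbind(t * dir[1] + stats::rnorm(n_col, 0, 0.05),
            t * dir[2] + stats::rnorm(n_col, 0, 0.05), t * dir[3])
  }
  do.call(rbind, pts)
}

# Pixel-center ray tangents for a pinhole model: lateral offset per unit
# boresight depth for every pixel, plus pixel indexing helpers.
pixel_rays <- function(spec) {
  ht <- half_tangents(spec)
  u <- ((seq_len(spec$n_cols) - 0.5) / spec$n_cols * 2 - 1) * ht[1]
  v <- ((seq_len(spec$n_rows) - 0.5) / spec$n_rows * 2 - 1) * ht[2]
  list(u = rep(u, each = spec$n_rows), v = rep(v, spec$n_cols), ht = ht)
}

# Boresight depth at which each pixel ray meets the terrain plane, or Inf.
terrain_depth <- function(rays, pose, terrain) {
  d_sensor <- cbind(rays$u, rays$v, 1)
  w <- d_sensor %*% t(pose$rotation)  # world direction per unit depth
  o <- pose$origin
  denom <- w[, 3] - terrain$slope_x * w[, 1] - terrain$slope_y * w[, 2]
  num <- terrain$z0 + terrain$slope_x * o[1] + terrain$slope_y * o[2] - o[3]
  t <- num / denom
  t[!is.finite(t) | t <= 0] <- Inf
  list(t = t, w = w)
}

#' Render a depth-camera frame of a synthetic field
#'
#' Simulates one time-of-flight frame: one ray per pixel through a pinhole
#' model, nearest-surface z-buffering of the plant surface splats against
#' the analytically intersected terrain plane, range limits, range noise and
#' bias along the ray, and optional measurement artefacts.
#'
#' The sensor does not resolve structures much finer than a pixel footprint.
#' Per pixel, the splats of the nearest surface cluster (within
#' `cluster_gap` of the nearest splat depth) are accepted only if their
#' summed ray-projected area reaches `fill_fraction` of the pixel footprint
#' at that depth; the returned depth is the area-weighted mean depth of the
#' cluster, which mixes the range across the footprint the way a TOF pixel
#' integrates its signal. Sub-pixel structures (fine plant apices) are
#' therefore measured slightly too low or missed - the mechanism behind the
#' systematic crop-height underestimation of such sensors. An accepted
#' cluster occludes the terrain; pixels with no accepted cluster fall
#' through to the terrain return.
#'
#' @param field a `synthetic_field`, or `NULL` for an empty scene (artefacts
#'   only)
#' @param pose the `sensor_pose` (above the canopy for field scenes)
#' @param spec a `frustum_spec`
#' @param noise a `noise_model` (use [noise_none()] to disable)
#' @param artefacts an `artefact_model` or `NULL`
#' @param seed integer seed (noise and artefacts)
#' @param splats optional precomputed [sample_field_surface] result
#' @param fill_fraction minimum pixel-fill fraction for a surface return
#' @param cluster_gap depth window grouping splats into one surface (m)
#' @param spacing surface sampling spacing if `splats` is not given (m)
#' @return a `point_cloud` with attribute `artefact` (logical); at most
#'   `n_cols * n_rows` surface points plus the artefact points
#' @export
render_depth_frame <- function(field, pose, spec = frustum_spec(),
                               noise = noise_model(), artefacts = NULL,
                               seed = 1L, splats = NULL,
                               fill_fraction = 0.5, cluster_gap = 0.05,
                               spacing = 0.004) {
  stopifnot(inherits(pose, "sensor_pose"), inherits(spec, "frustum_spec"))
  rays <- pixel_rays(spec)
  npix <- length(rays$u)
  depth <- rep(Inf, npix)

  if (!is.null(field)) {
    td <- terrain_depth(rays, pose, field$terrain)
    depth <- td$t

    if (is.null(splats)) splats <- sample_field_surface(field, spacing)
    if (nrow(splats$xyz) > 0) {
      s <- to_sensor_frame(splats$xyz, pose)
      ht <- rays$ht
      inside <- s[, 3] > 1e-6 &
        abs(s[, 1]) <= s[, 3] * ht[1] & abs(s[, 2]) <= s[, 3] * ht[2]
      if (any(inside)) {
        sx <- s[inside, 1]; sy <- s[inside, 2]; sz <- s[inside, 3]
        col <- pmin(spec$n_cols,
                    pmax(1L, floor((sx / (sz * ht[1]) + 1) / 2 *
                                     spec$n_cols) + 1L))
        row <- pmin(spec$n_rows,
                    pmax(1L, floor((sy / (sz * ht[2]) + 1) / 2 *
                                     spec$n_rows) + 1L))
        pix <- (col - 1L) * spec$n_rows + row
        # ray-projected splat area (visible cross-section)
        v <- sweep(splats$xyz[inside, , drop = FALSE], 2, pose$origin, `-`)
        rng <- sqrt(rowSums(v^2))
        wgt <- splats$area[inside] *
          abs(rowSums(v * splats$normal[inside, , drop = FALSE])) / rng
        # pixel footprint area grows quadratically with depth
        pix_area_coef <- (2 * ht[1] / spec$n_cols) * (2 * ht[2] / spec$n_rows)

        active <- rep(TRUE, length(pix))
        for (pass in 1:2) {
          if (!any(active)) break
          idx <- which(active)
          ord <- idx[order(pix[idx], sz[idx])]
          firsts <- !duplicated(pix[ord])
          upix <- pix[ord][firsts]
          z1 <- sz[ord][firsts]
          z1_all <- z1[match(pix[idx], upix)]
          in_cl <- sz[idx] <= z1_all + cluster_gap
          ci <- idx[in_cl]
          cov <- rowsum(wgt[ci], pix[ci])
          wz <- rowsum(wgt[ci] * sz[ci], pix[ci])
          gpix <- as.integer(rownames(cov))
          gz1 <- z1[match(gpix, upix)]
          ok <- cov[, 1] >= fill_fraction * pix_area_coef * gz1^2
          zret <- wz[ok, 1] / cov[ok, 1]
          accept <- gpix[ok] ; zacc <- zret
          better <- zacc < depth[accept]
          depth[accept[better]] <- zacc[better]
          # failed pixels: drop their nearest cluster and retry once
          failed <- gpix[!ok]
          active[ci] <- FALSE
          active[idx] <- active[idx] & pix[idx] %in% failed
        }
      }
    }
  }

  keep <- is.finite(depth) & depth >= spec$min_range & depth <= spec$max_range
  d_sensor <- cbind(rays$u[keep], rays$v[keep], rep(1, sum(keep)))
  dep <- depth[keep]
  norm_d <- sqrt(rowSums(d_sensor^2))
  rng <- dep * norm_d

  art_s <- matrix(numeric(0), 0, 3)
  with_seed(seed, {
    if (length(rng) > 0) {
      rng <- rng + noise_bias(noise, rng) +
        stats::rnorm(length(rng), 0, noise_sd(noise, rng))
    }
    if (!is.null(artefacts)) art_s <- draw_artefacts(artefacts, spec)
  })
  surf_s <- d_sensor * (rng / norm_d)
  xyz_s <- rbind(surf_s, art_s)
  flag <- c(rep(FALSE, nrow(surf_s)), rep(TRUE, nrow(art_s)))
  if (nrow(xyz_s) == 0) {
    pc <- point_cloud(matrix(numeric(0), 0, 3))
    pc$attrs$artefact <- logical(0)
    return(pc)
  }
  point_cloud(to_world_frame(xyz_s, pose), artefact = flag)
}

#' Render a terrestrial-laser-scanner view of a synthetic field
#'
#' Simulates a tripod scanner: a spherical grid of rays at the given angular
#' resolution, first-return z-buffering of the plant splats against the
#' analytic terrain, and Gaussian range noise. Unlike the depth camera, no
#' pixel-fill criterion is applied: the narrow laser beam resolves fine
#' structures such as plant apices, which is what makes the instrument the
#' reference.
#'
#' @param field a `synthetic_field`
#' @param origin scanner position `c(x, y, z)` in meters
#' @param angular_resolution angular step in degrees (default 0.029)
#' @param range_sd range noise SD in meters (default 0.003)
#' @param seed integer seed
#' @param splats optional precomputed [sample_field_surface] result
#' @param window optional `c(az_min, az_max, el_min, el_max)` in radians
#'   relative to nothing (absolute angles); computed from the field extent
#'   when `NULL`
#' @param margin extra ground margin around the plot kept in the scan (m)
#' @param spacing surface sampling spacing if `splats` is not given (m)
#' @return a `point_cloud`
#' @export
render_tls_scan <- function(field, origin, angular_resolution = 0.029,
                            range_sd = 0.003, seed = 1L, splats = NULL,
                            window = NULL, margin = 0.3, spacing = 0.004) {
  stopifnot(inherits(field, "synthetic_field"), length(origin) == 3)
  res <- deg2rad(angular_resolution)
  ex <- field$extent
  if (is.null(window)) {
    cx <- c(-margin, ex[1] + margin); cy <- c(-margin, ex[2] + margin)
    corners <- as.matrix(expand.grid(x = cx, y = cy))
    zg <- terrain_z(field$terrain, corners[, 1], corners[, 2])
    hmax <- max(field$plants$height)
    pts <- rbind(cbind(corners, zg), cbind(corners, zg + hmax))
    v <- sweep(pts, 2, origin, `-`)
    az <- atan2(v[, 2], v[, 1])
    az0 <- atan2(mean(sin(az)), mean(cos(az)))
    daz <- ((az - az0 + pi) %% (2 * pi)) - pi
    el <- atan2(v[, 3], sqrt(v[, 1]^2 + v[, 2]^2))
    pad <- deg2rad(1)
    window <- c(az0 + min(daz) - pad, az0 + max(daz) + pad,
                min(el) - pad, max(el) + pad)
  }
  az_seq <- seq(window[1], window[2], by = res)
  el_seq <- seq(window[3], window[4], by = res)
  n_az <- length(az_seq); n_el <- length(el_seq)

  # analytic terrain return per ray
  AZ <- rep(az_seq, each = n_el)
  EL <- rep(el_seq, n_az)
  dx <- cos(EL) * cos(AZ); dy <- cos(EL) * sin(AZ); dz <- sin(EL)
  tr <- field$terrain
  denom <- dz - tr$slope_x * dx - tr$slope_y * dy
  num <- tr$z0 + tr$slope_x * origin[1] + tr$slope_y * origin[2] - origin[3]
  t_terr <- num / denom
  t_terr[!is.finite(t_terr) | t_terr <= 0] <- Inf
  gx <- origin[1] + t_terr * dx
  gy <- origin[2] + t_terr * dy
  on_ground <- is.finite(t_terr) &
    gx >= -margin & gx <= ex[1] + margin &
    gy >= -margin & gy <= ex[2] + margin
  t_terr[!on_ground] <- Inf

  # plant splats, binned on the angular grid, first return per cell
  if (is.null(splats)) splats <- sample_field_surface(field, spacing)
  v <- sweep(splats$xyz, 2, origin, `-`)
  rng <- sqrt(rowSums(v^2))
  saz <- atan2(v[, 2], v[, 1])
  sel <- atan2(v[, 3], sqrt(v[, 1]^2 + v[, 2]^2))
  daz <- ((saz - window[1]) %% (2 * pi))
  ia <- floor(daz / res + 0.5) + 1L
  ie <- floor((sel - window[3]) / res + 0.5) + 1L
  okb <- ia >= 1 & ia <= n_az & ie >= 1 & ie <= n_el
  cell <- (ia[okb] - 1L) * n_el + ie[okb]
  rr <- rng[okb]
  ord <- order(cell, rr)
  firsts <- !duplicated(cell[ord])
  pcell <- cell[ord][firsts]
  pidx <- which(okb)[ord][firsts]
  prng <- rr[ord][firsts]

  plant_hit <- prng < t_terr[pcell]
  t_terr[pcell[plant_hit]] <- Inf  # occluded terrain

  keep_t <- is.finite(t_terr)
  with_seed(seed, {
    tn <- t_terr[keep_t] + stats::rnorm(sum(keep_t), 0, range_sd)
    pn <- prng[plant_hit] + stats::rnorm(sum(plant_hit), 0, range_sd)
  })
  terr_pts <- cbind(origin[1] + tn * dx[keep_t],
                    origin[2] + tn * dy[keep_t],
                    origin[3] + tn * dz[keep_t])
  pi_sel <- pidx[plant_hit]
  u <- v[pi_sel, , drop = FALSE] / rng[pi_sel]
  plant_pts <- sweep(u * pn, 2, origin, `+`)
  point_cloud(rbind(terr_pts, plant_pts),
              surface = c(rep("terrain", nrow(terr_pts)),
                          rep("plant", nrow(plant_pts))))
}

#' Render a virtual scan of a planar target
#'
#' Simulates a depth-camera scan of an orthogonal planar target at the given
#' boresight range, as used in lab characterization of precision and
#' accuracy. The cloud is returned in the sensor frame (z = boresight
#' depth), ready for [plane_precision_accuracy].
#'
#' @param range target depth in meters
#' @param spec a `frustum_spec`
#' @param noise a `noise_model`
#' @param seed integer seed
#' @return a `point_cloud` in the sensor frame
#' @export
render_plane_scan <- function(range, spec = frustum_spec(),
                              noise = noise_model(), seed = 1L) {
  stopifnot(range > 0)
  field <- generate_field(n_plants = 1, extent = c(0.1, 0.1),
                          spacing_long = 0.05, spacing_trans = 0.05,
                          height_range = c(1e-6, 1e-6), seed = 1L)
  field$plants <- field$plants[0, ]
  pose <- nadir_pose(0, 0, range)
  # a plane at z = 0 viewed from straight above 'range' meters away
  frame <- render_depth_frame(field, pose, spec, noise, seed = seed,
                              splats = list(xyz = matrix(numeric(0), 0, 3),
                                            normal = matrix(numeric(0), 0, 3),
                                            area = numeric(0)))
  out <- frame
  out$xyz <- to_sensor_frame(frame$xyz, pose)
  out
}

#' Simulate the default single-campaign survey of a synthetic field
#'
#' Renders 8 nadir depth-camera frames whose positions advance monotonically
#' along the plot's long axis with overlapping footprints, each mounted a
#' fixed clearance above the locally highest plant (averaging about 3.75 m
#' above ground on the default field), plus 5 terrestrial laser scans from
#' elevated positions around the plot, merged into one reference cloud.
#' Everything is expressed in one world frame with known ground truth.
#'
#' @param field a `synthetic_field`
#' @param seed integer seed; frame and scan seeds are derived from it
#' @param spec the depth camera `frustum_spec`
#' @param noise the depth camera `noise_model`
#' @param artefacts optional `artefact_model` applied to every frame
#' @param clearance sensor height above the locally highest plant (m)
#' @param n_frames number of depth-camera positions (default 8)
#' @param tls_resolution TLS angular step in degrees used for the campaign
#'   (default 0.12, a tractable sub-centimeter point spacing at plot scale)
#' @param tls_range_sd TLS range noise SD (m)
#' @param spacing surface sampling spacing (m)
#' @return an object of class `campaign`: `k2_frames` (list of
#'   `point_cloud`), `k2_poses`, `top_ranges`, `tls_scans` (list),
#'   `tls_reference` (merged `point_cloud`), `field`, `spec`, `aoi`
#' @export
default_campaign <- function(field, seed = 1L, spec = frustum_spec(),
                             noise = noise_model(), artefacts = NULL,
                             clearance = 2.05, n_frames = 8L,
                             tls_resolution = 0.12, tls_range_sd = 0.003,
                             spacing = 0.004) {
  stopifnot(inherits(field, "synthetic_field"))
  ex <- field$extent
  splats <- sample_field_surface(field, spacing)
  ht <- half_tangents(spec)
  half_len <- clearance * ht[2]  # frame half-footprint along y at canopy top

  ys <- seq(0.6, ex[2] - 0.6, length.out = n_frames)
  poses <- vector("list", n_frames)
  frames <- vector("list", n_frames)
  top_ranges <- numeric(n_frames)
  for (i in seq_len(n_frames)) {
    near <- abs(field$plants$y - ys[i]) <= half_len + 0.2
    local_top <- if (any(near))
      max(field$plants$height[near] +
            terrain_z(field$terrain, field$plants$x[near],
                      field$plants$y[near]))
    else terrain_z(field$terrain, ex[1] / 2, ys[i])
    poses[[i]] <- nadir_pose(ex[1] / 2, ys[i], local_top + clearance)
    top_ranges[i] <- clearance
    frames[[i]] <- render_depth_frame(field, poses[[i]], spec, noise,
                                      artefacts, seed = seed + i,
                                      splats = splats)
  }

  zs <- 3.5
  tls_origins <- list(c(ex[1] / 2, -2.0, zs),
                      c(-2.0, 0.25 * ex[2], zs),
                      c(ex[1] + 2.0, 0.5 * ex[2], zs),
                      c(-2.0, 0.75 * ex[2], zs),
                      c(ex[1] / 2, ex[2] + 2.0, zs))
  tls_scans <- lapply(seq_along(tls_origins), function(j) {
    render_tls_scan(field, tls_origins[[j]],
                    angular_resolution = tls_resolution,
                    range_sd = tls_range_sd, seed = seed + 100L + j,
                    splats = splats)
  })
  structure(list(k2_frames = frames, k2_poses = poses,
                 top_ranges = top_ranges, tls_scans = tls_scans,
                 tls_reference = merge_clouds(tls_scans,
                                              ids = paste0("tls", seq_along(tls_scans))),
                 field = field, spec = spec,
                 aoi = c(0, 0, ex[1], ex[2]), seed = seed),
            class = "campaign")
}

#' @export
print.campaign <- function(x, ...) {
  cat(sprintf("campaign: %d depth frames (%s pts), %d TLS scans (%d pts ref), %d plants\n",
              length(x$k2_frames),
              paste(vapply(x$k2_frames, n_points, integer(1)),
                    collapse = "/"),
              length(x$tls_scans), n_points(x$tls_reference),
              nrow(x$field$plants)))
  invisible(x)
}
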