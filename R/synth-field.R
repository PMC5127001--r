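#' Terrain surface of a synthetic field
#'
#' A plane `z = z0 + slope_x * x + slope_y * y`. Kept analytic so renderers
#' can intersect rays with it exactly.
#'
#' @param z0 elevation at the origin (m)
#' @param slope_x,slope_y terrain gradients (m/m)
#' @return an object of class `terrain_model`
#' @export
terrain_model <- function(z0 = 0, slope_x = 0, slope_y = 0) {
  structure(list(z0 = z0, slope_x = slope_x, slope_y = slope_y),
            class = "terrain_model")
}

#' Terrain elevation at coordinates
#' @param terrain a `terrain_model`
#' @param x,y coordinates in meters
#' @return elevations in meters
#' @export
terrain_z <- function(terrain, x, y) {
  terrain$z0 + terrain$slope_x * x + terrain$slope_y * y
}

#' Generate a synthetic maize field
#'
#' Lays out plants on a jittered regular grid inside the plot extent and
#' assigns heights increasing along y (emulating a south-to-north growth
#' gradient caused by shading at the southern edge), linearly rescaled so
#' the configured height range is spanned exactly. The default emulates the
#' study plot: 52 plants on a 2.5 m x 8.0 m plot, mean longitudinal (y)
#' spacing 0.58 m, mean transverse (x) spacing 0.46 m, heights from 0.55 m
#' to 2.41 m. Reproducible for a given seed.
#'
#' @param n_plants number of plants (default 52)
#' @param extent plot extent `c(width_x, length_y)` in meters
#' @param spacing_long mean longitudinal (y) plant spacing (m)
#' @param spacing_trans mean transverse (x) plant spacing (m)
#' @param height_range `c(min, max)` plant heights (m)
#' @param jitter positional jitter half-range (m)
#' @param terrain a `terrain_model`
#' @param shape stylized plant-shape parameters; see Details
#' @param seed integer seed
#' @return an object of class `synthetic_field`: `plants` (data.frame `id`,
#'   `x`, `y`, `height`, `n_leaves`, `azimuth0`), `extent`, `terrain`,
#'   `shape`, `seed`
#' @details The plant shape is a stylized geometric stand-in for maize
#'   morphology: a tapered vertical stem (base radius `stem_radius`
#'   narrowing to `tip_radius` over the top `taper_length`) whose apex sits
#'   exactly at the plant height over terrain, plus `n_leaves` arched blades
#'   (`leaf_width` wide at the base) radiating from the stem. It is not a
#'   botanical model; it exists to create occlusion, canopy gaps and fine
#'   apices, the surface features the height-derivation method depends on.
#' @export
generate_field <- function(n_plants = 52L, extent = c(2.5, 8.0),
                           spacing_long = 0.58, spacing_trans = 0.46,
                           height_range = c(0.55, 2.41), jitter = 0.02,
                           terrain = terrain_model(),
                           shape = list(stem_radius = 0.012,
                                        tip_radius = 0.003,
                                        taper_length = 0.30,
                                        leaf_width = 0.045),
                           seed = 1L) {
  stopifnot(n_plants >= 1, length(extent) == 2, all(extent > 0),
            height_range[1] > 0, height_range[2] >= height_range[1])
  if (spacing_trans > extent[1] || spacing_long > extent[2])
    stop("plant spacing exceeds the plot extent")
  with_seed(seed, {
    if (n_plants == 1) {
      px <- extent[1] / 2
      py <- extent[2] / 2
    } else {
      ncol_p <- max(1L, floor(extent[1] / spacing_trans))
      nrow_p <- ceiling(n_plants / ncol_p)
      if ((nrow_p - 1) * spacing_long > extent[2])
        stop("infeasible spacing/extent combination for ", n_plants,
             " plants")
      x0 <- (extent[1] - (ncol_p - 1) * spacing_trans) / 2
      y0 <- (extent[2] - (nrow_p - 1) * spacing_long) / 2
      gx <- x0 + spacing_trans * (seq_len(ncol_p) - 1)
      gy <- y0 + spacing_long * (seq_len(nrow_p) - 1)
      grid <- expand.grid(x = gx, y = gy)
      grid <- grid[order(grid$y, grid$x), ][seq_len(n_plants), ]
      px <- grid$x + stats::runif(n_plants, -jitter, jitter)
      py <- grid$y + stats::runif(n_plants, -jitter, jitter)
      px <- pmin(pmax(px, 0.05), extent[1] - 0.05)
      py <- pmin(pmax(py, 0.05), extent[2] - 0.05)
    }
    u <- (py - min(py)) / max(max(py) - min(py), 1e-9)
    h <- height_range[1] + (height_range[2] - height_range[1]) * u +
      stats::rnorm(n_plants, 0, 0.06)
    if (n_plants > 1 && max(h) > min(h)) {
      h <- (h - min(h)) / (max(h) - min(h))
      h <- height_range[1] + (height_range[2] - height_range[1]) * h
    } else {
      h <- rep(mean(height_range), n_plants)
    }
    plants <- data.frame(
      id = seq_len(n_plants), x = px, y = py, height = h,
      n_leaves = 6L + as.integer(h > 1.5),
      azimuth0 = stats::runif(n_plants, 0, 2 * pi))
  })
  structure(list(plants = plants, extent = as.numeric(extent),
                 terrain = terrain, shape = shape, seed = seed),
            class = "synthetic_field")
}

#' @export
print.synthetic_field <- function(x, ...) {
  cat(sprintf("synthetic_field: %d plants on %.1f x %.1f m, heights [%.2f, %.2f] m (seed %d)\n",
              nrow(x$plants), x$extent[1], x$extent[2],
              min(x$plants$height), max(x$plants$height), x$seed))
  invisible(x)
}

#' Write the ground-truth plant table as CSV
#' @param field a `synthetic_field`
#' @param path output CSV path
#' @return `path`, invisibly
#' @export
write_field_truth <- function(field, path) {
  utils::write.csv(field$plants[, c("id", "x", "y", "height")], path,
                   row.names = FALSE)
  invisible(path)
}

# Surface splats of one plant: positions, outward unit normals and surface
# areas (m^2). The splat set is a dense, deterministic sampling of the
# stylized plant surface used by both virtual sensors.
sample_plant_surface <- function(px, py, h, zg, shape, n_leaves, azimuth0,
                                 spacing, plant_seed) {
  R0 <- shape$stem_radius
  Rt <- shape$tip_radius
  taper <- min(shape$taper_length, 0.8 * h)
  out_xyz <- list(); out_nrm <- list(); out_area <- list()

  # stem: rings up the tapered cylinder
  zu <- seq(0, h - spacing / 2, by = spacing)
  r <- ifelse(zu < h - taper, R0, Rt + (R0 - Rt) * (h - zu) / taper)
  m <- max(6L, ceiling(2 * pi * R0 / spacing))
  ang <- 2 * pi * (seq_len(m) - 1) / m
  ZU <- rep(zu, each = m)
  RR <- rep(r, each = m)
  CA <- rep(cos(ang), length(zu))
  SA <- rep(sin(ang), length(zu))
  out_xyz[[1]] <- cbind(px + RR * CA, py + RR * SA, zg + ZU)
  out_nrm[[1]] <- cbind(CA, SA, 0)
  out_area[[1]] <- rep(2 * pi * r * spacing / m, each = m)

  # apex cap: a small disc at the exact plant height
  nc <- max(1L, round(pi * Rt^2 / spacing^2))
  kk <- seq_len(nc)
  rr <- Rt * sqrt((kk - 0.5) / nc)
  aa <- kk * 2.399963  # golden angle
  out_xyz[[2]] <- cbind(px + rr * cos(aa), py + rr * sin(aa), zg + h)
  out_nrm[[2]] <- cbind(rep(0, nc), rep(0, nc), rep(1, nc))
  out_area[[2]] <- rep(pi * Rt^2 / nc, nc)

  # leaves: arched blades radiating from the stem
  leaf <- with_seed(plant_seed, {
    list(a = 0.9 + stats::runif(n_leaves, -0.15, 0.15),
         az = azimuth0 + (seq_len(n_leaves) - 1) * 2.399963 +
           stats::runif(n_leaves, -0.2, 0.2),
         uj = h * (0.20 + 0.60 * (seq_len(n_leaves) - 1) /
                     max(1, n_leaves - 1)) *
           (1 + stats::runif(n_leaves, -0.05, 0.05)),
         Tl = (0.25 * h + 0.10) * (1 + stats::runif(n_leaves, -0.1, 0.1)))
  })
  w0 <- shape$leaf_width
  k <- 3L
  for (j in seq_len(n_leaves)) {
    a <- leaf$a[j]; Tl <- leaf$Tl[j]; uj <- leaf$uj[j]; phi <- leaf$az[j]
    b <- a / Tl
    dt <- spacing * 0.8
    t <- seq(dt / 2, Tl, by = dt)
    slope <- a - 2 * b * t
    ds <- sqrt(1 + slope^2) * dt
    w <- pmax(0.006, w0 * (1 - t / Tl))
    nw <- pmax(1L, ceiling(w / spacing))
    rep_t <- rep(t, nw); rep_ds <- rep(ds, nw); rep_w <- rep(w, nw)
    rep_slope <- rep(slope, nw); rep_nw <- rep(nw, nw)
    lat <- (sequence(nw) - (rep_nw + 1) / 2) / rep_nw * rep_w
    cphi <- cos(phi); sphi <- sin(phi)
    x <- px + rep_t * cphi - lat * sphi
    y <- py + rep_t * sphi + lat * cphi
    z <- zg + uj + a * rep_t - b * rep_t^2
    nn <- sqrt(1 + rep_slope^2)
    out_xyz[[k]] <- cbind(x, y, z)
    out_nrm[[k]] <- cbind(-rep_slope * cphi / nn, -rep_slope * sphi / nn,
                          1 / nn)
    out_area[[k]] <- rep_ds * rep_w / rep_nw
    k <- k + 1L
  }
  list(xyz = do.call(rbind, out_xyz),
       normal = do.call(rbind, out_nrm),
       area = unlist(out_area, use.names = FALSE))
}

#' Sample the surface of a synthetic field as splats
#'
#' Densely samples every plant surface into "splats": positions, outward
#' unit normals and the surface area each sample represents. The splat set
#' is the geometry input of both virtual sensors; terrain is intersected
#' analytically and never splatted. Deterministic given the field.
#'
#' @param field a `synthetic_field`
#' @param spacing sample spacing on the surface in meters (default 0.004,
#'   i.e. finer than the depth-camera pixel footprint at working range)
#' @return list with `xyz` (n x 3), `normal` (n x 3), `area` (length n),
#'   `plant_id` (length n)
#' @export
sample_field_surface <- function(field, spacing = 0.004) {
  stopifnot(inherits(field, "synthetic_field"), spacing > 0)
  p <- field$plants
  if (nrow(p) == 0) {
    return(list(xyz = matrix(numeric(0), 0, 3),
                normal = matrix(numeric(0), 0, 3),
                area = numeric(0), plant_id = integer(0)))
  }
  parts <- vector("list", nrow(p))
  for (i in seq_len(nrow(p))) {
    zg <- terrain_z(field$terrain, p$x[i], p$y[i])
    parts[[i]] <- sample_plant_surface(p$x[i], p$y[i], p$height[i], zg,
                                       field$shape, p$n_leaves[i],
                                       p$azimuth0[i], spacing,
                                       plant_seed = (field$seed %% 1000003L) *
                                         1009L + p$id[i])
  }
  ns <- vapply(parts, function(q) nrow(q$xyz), integer(1))
  list(xyz = do.call(rbind, lapply(parts, `[[`, "xyz")),
       normal = do.call(rbind, lapply(parts, `[[`, "normal")),
       area = unlist(lapply(parts, `[[`, "area"), use.names = FALSE),
       plant_id = rep(p$id, ns))
}
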