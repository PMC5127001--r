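#' Regular raster grid of elevations or heights
#'
#' Cells are half-open: cell `(i, j)` covers
#' `[x0 + (j-1) s, x0 + j s) x [y0 + (i-1) s, y0 + i s)`, except that points
#' exactly on the grid's maximum x or y edge are assigned to the last cell,
#' so every point inside the closed extent maps to exactly one cell. `NA`
#' marks nodata cells. Values are stored as a matrix with rows along y
#' (row 1 at the southern, origin edge) and columns along x.
#'
#' @param origin numeric `(x, y)` of the lower-left corner, meters
#' @param cell_size cell edge length in meters (> 0)
#' @param values numeric matrix `n_rows x n_cols` (`NA` = nodata)
#' @return an object of class `raster_grid`
#' @export
raster_grid <- function(origin, cell_size, values) {
  stopifnot(length(origin) == 2, cell_size > 0, is.matrix(values))
  structure(list(origin = as.numeric(origin), cell_size = cell_size,
                 values = values), class = "raster_grid")
}

#' Define an empty raster grid covering a rectangular extent
#' @param xmin,ymin,xmax,ymax extent in meters
#' @param cell_size cell edge length in meters
#' @return an all-nodata `raster_grid` whose extent covers the box
#' @export
raster_grid_def <- function(xmin, ymin, xmax, ymax, cell_size = 0.25) {
  stopifnot(xmin < xmax, ymin < ymax, cell_size > 0)
  nc <- max(1L, as.integer(ceiling((xmax - xmin) / cell_size - 1e-9)))
  nr <- max(1L, as.integer(ceiling((ymax - ymin) / cell_size - 1e-9)))
  raster_grid(c(xmin, ymin), cell_size,
              matrix(NA_real_, nrow = nr, ncol = nc))
}

#' @export
print.raster_grid <- function(x, ...) {
  v <- x$values
  cat(sprintf("raster_grid: %d x %d cells of %g m, origin (%g, %g), %d valid\n",
              nrow(v), ncol(v), x$cell_size, x$origin[1], x$origin[2],
              sum(!is.na(v))))
  if (any(!is.na(v)))
    cat(sprintf("  values: [%.3f, %.3f] m\n", min(v, na.rm = TRUE),
                max(v, na.rm = TRUE)))
  invisible(x)
}

#' Number of valid (non-nodata) cells
#' @param grid a `raster_grid`
#' @return integer count
#' @export
valid_cells <- function(grid) {
  stopifnot(inherits(grid, "raster_grid"))
  sum(!is.na(grid$values))
}

grids_aligned <- function(a, b) {
  all(abs(a$origin - b$origin) < 1e-9) &&
    abs(a$cell_size - b$cell_size) < 1e-12 &&
    all(dim(a$values) == dim(b$values))
}

# Cell indices (row i along y, col j along x) for coordinates; points on the
# grid's max edge are folded into the last cell; NA outside the extent.
cell_index <- function(grid, x, y) {
  s <- grid$cell_size
  nr <- nrow(grid$values); nc <- ncol(grid$values)
  xmax <- grid$origin[1] + nc * s
  ymax <- grid$origin[2] + nr * s
  j <- floor((x - grid$origin[1]) / s) + 1
  i <- floor((y - grid$origin[2]) / s) + 1
  j[x == xmax] <- nc
  i[y == ymax] <- nr
  ok <- i >= 1 & i <= nr & j >= 1 & j <= nc
  i[!ok] <- NA; j[!ok] <- NA
  list(row = i, col = j)
}

#' Rasterize a point cloud by per-cell extreme elevation
#'
#' Assigns to every grid cell the maximum (`mode = "max"`, the digital
#' surface model convention) or minimum (`mode = "min"`, the digital terrain
#' model convention) z of the points falling in it. Cells containing no
#' points are nodata. No interpolation is performed: the method relies on
#' canopy gaps exposing the ground so that per-cell minima sample the
#' terrain directly.
#'
#' @param cloud a `point_cloud`
#' @param grid a `raster_grid` defining origin, cell size and shape (e.g.
#'   from [raster_grid_def]); its values are ignored
#' @param mode `"max"` or `"min"`
#' @return a `raster_grid` of per-cell extremes
#' @export
rasterize_extreme <- function(cloud, grid, mode = c("max", "min")) {
  stopifnot(inherits(cloud, "point_cloud"), inherits(grid, "raster_grid"))
  mode <- match.arg(mode)
  v <- matrix(NA_real_, nrow(grid$values), ncol(grid$values))
  out <- raster_grid(grid$origin, grid$cell_size, v)
  if (n_points(cloud) == 0) {
    warning("empty cloud: returning all-nodata grid")
    return(out)
  }
  idx <- cell_index(grid, cloud$xyz[, 1], cloud$xyz[, 2])
  keep <- !is.na(idx$row)
  if (!any(keep)) return(out)
  lin <- (idx$col[keep] - 1L) * nrow(v) + idx$row[keep]
  z <- cloud$xyz[keep, 3]
  ord <- order(lin, if (mode == "max") -z else z)
  first <- !duplicated(lin[ord])
  out$values[lin[ord][first]] <- z[ord][first]
  out
}

#' Derive a crop height model from DSM and DTM
#'
#' Cellwise `DSM - DTM`; nodata in either input propagates. When both
#' rasters come from the same cloud the result is non-negative by
#' construction.
#'
#' @param dsm,dtm aligned `raster_grid` objects
#' @return a `raster_grid` of canopy heights (meters)
#' @export
derive_chm <- function(dsm, dtm) {
  stopifnot(inherits(dsm, "raster_grid"), inherits(dtm, "raster_grid"))
  if (!grids_aligned(dsm, dtm)) stop("DSM and DTM grids are not aligned")
  raster_grid(dsm$origin, dsm$cell_size, dsm$values - dtm$values)
}

#' Mask the outermost raster cells
#'
#' Sets the outermost `rings` cell ring(s) to nodata, keeping the grid
#' extent (so all rasters stay co-registered). Border cells are typically
#' covered only partly by the point cloud and would bias the height
#' statistics.
#'
#' @param grid a `raster_grid` with more than `2 * rings` rows and columns
#' @param rings number of rings to mask (default 1)
#' @return the masked `raster_grid`
#' @export
trim_border <- function(grid, rings = 1L) {
  stopifnot(inherits(grid, "raster_grid"))
  nr <- nrow(grid$values); nc <- ncol(grid$values)
  if (nr <= 2 * rings || nc <= 2 * rings)
    stop("grid too small to trim ", rings, " ring(s)")
  v <- grid$values
  b <- seq_len(rings)
  v[c(b, nr + 1 - b), ] <- NA_real_
  v[, c(b, nc + 1 - b)] <- NA_real_
  raster_grid(grid$origin, grid$cell_size, v)
}

#' Cellwise difference of two aligned rasters
#'
#' Computes `test - reference` per cell, so positive values mean the test
#' raster is higher than the reference. Nodata in either input propagates.
#'
#' @param test,reference aligned `raster_grid` objects
#' @return a `raster_grid` of differences
#' @export
difference_raster <- function(test, reference) {
  stopifnot(inherits(test, "raster_grid"), inherits(reference, "raster_grid"))
  if (!grids_aligned(test, reference)) stop("grids are not aligned")
  raster_grid(test$origin, test$cell_size, test$values - reference$values)
}

#' Build the DSM/DTM/CHM triple for a cloud
#'
#' Rasterizes per-cell maxima (DSM) and minima (DTM), derives the CHM as
#' their difference and masks the outermost CHM ring(s).
#'
#' @param cloud a `point_cloud`
#' @param grid a `raster_grid` defining the target grid
#' @param trim_rings border rings to mask on the CHM (0 to disable)
#' @return an object of class `chm_set`: list with `dsm`, `dtm`, `chm`
#' @export
build_chm_set <- function(cloud, grid, trim_rings = 1L) {
  dsm <- rasterize_extreme(cloud, grid, "max")
  dtm <- rasterize_extreme(cloud, grid, "min")
  chm <- derive_chm(dsm, dtm)
  if (trim_rings > 0) chm <- trim_border(chm, trim_rings)
  structure(list(dsm = dsm, dtm = dtm, chm = chm), class = "chm_set")
}

#' @export
print.chm_set <- function(x, ...) {
  cat("chm_set\n  DSM: "); print(x$dsm)
  cat("  DTM: "); print(x$dtm)
  cat("  CHM: "); print(x$chm)
  invisible(x)
}

#' Write a raster as an ESRI ASCII grid
#'
#' North-up row order, `NODATA_value -9999`, cell values in meters.
#'
#' @param grid a `raster_grid`
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_esri_ascii <- function(grid, path) {
  stopifnot(inherits(grid, "raster_grid"))
  v <- grid$values
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("ncols %d", ncol(v)),
               sprintf("nrows %d", nrow(v)),
               sprintf("xllcorner %.10g", grid$origin[1]),
               sprintf("yllcorner %.10g", grid$origin[2]),
               sprintf("cellsize %.10g", grid$cell_size),
               "NODATA_value -9999"), con)
  for (i in rev(seq_len(nrow(v)))) {
    row <- v[i, ]
    row[is.na(row)] <- -9999
    writeLines(paste(formatC(row, format = "g", digits = 10),
                     collapse = " "), con)
  }
  invisible(path)
}

#' Read an ESRI ASCII grid
#' @param path file path
#' @return a `raster_grid` (nodata as `NA`)
#' @export
read_esri_ascii <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1
  while (i <= length(lines) &&
         grepl("^[a-zA-Z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% names(hdr)))
    stop("malformed ESRI ASCII header in ", path)
  nodata <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else -9999
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  if (length(vals) != hdr$ncols * hdr$nrows)
    stop("ESRI ASCII grid value count mismatch in ", path)
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  m <- m[rev(seq_len(nrow(m))), , drop = FALSE]  # back to south-first rows
  m[m == nodata] <- NA_real_
  raster_grid(c(hdr$xllcorner, hdr$yllcorner), hdr$cellsize, m)
}
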