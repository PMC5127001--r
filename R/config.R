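#' Processing-pipeline configuration
#'
#' Collects all tunable parameters of the processing chain with their
#' standard defaults: 0.25 m raster cells, 5-neighbor statistical outlier
#' removal with a 1.0 SD multiplier, 0.125 m plant search radius, 0.500 m
#' minimum plant height, blunder factor 3 and a 2.5 m x 8.0 m area of
#' interest.
#'
#' @param cell_size CHM raster cell size (m)
#' @param sor_k,sor_multiplier outlier-filter parameters
#' @param plant_radius horizontal plant search radius (m)
#' @param min_plant_height minimum accepted plant height (m)
#' @param blunder_factor RMSE multiplier defining blunders
#' @param aoi `c(xmin, ymin, xmax, ymax)` in meters
#' @param trim_rings CHM border rings to mask
#' @param frustum a `frustum_spec`
#' @param seed default seed for stochastic steps
#' @return an object of class `pipeline_config`
#' @export
pipeline_config <- function(cell_size = 0.25, sor_k = 5L,
                            sor_multiplier = 1.0, plant_radius = 0.125,
                            min_plant_height = 0.500, blunder_factor = 3,
                            aoi = c(0, 0, 2.5, 8.0), trim_rings = 1L,
                            frustum = frustum_spec(), seed = 1L) {
  stopifnot(cell_size > 0, sor_k >= 1, plant_radius > 0,
            min_plant_height >= 0, blunder_factor > 0, length(aoi) == 4,
            aoi[1] < aoi[3], aoi[2] < aoi[4])
  structure(list(cell_size = cell_size, sor_k = as.integer(sor_k),
                 sor_multiplier = sor_multiplier,
                 plant_radius = plant_radius,
                 min_plant_height = min_plant_height,
                 blunder_factor = blunder_factor, aoi = as.numeric(aoi),
                 trim_rings = as.integer(trim_rings), frustum = frustum,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat(sprintf(paste0("pipeline_config: cell %g m, SOR k=%d x%g, plant radius ",
                     "%g m, min height %g m,\n  blunders > %g RMSE, AOI ",
                     "[%g, %g] x [%g, %g] m, trim %d ring(s), seed %d\n"),
              x$cell_size, x$sor_k, x$sor_multiplier, x$plant_radius,
              x$min_plant_height, x$blunder_factor, x$aoi[1], x$aoi[3],
              x$aoi[2], x$aoi[4], x$trim_rings, x$seed))
  invisible(x)
}

#' Read / write a pipeline configuration as YAML
#'
#' @param path file path
#' @return `read_config`: a `pipeline_config`
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  fr <- if (!is.null(y$frustum))
    do.call(frustum_spec, y$frustum) else frustum_spec()
  y$frustum <- NULL
  do.call(pipeline_config, c(y, list(frustum = fr)))
}

#' @rdname read_config
#' @param config a `pipeline_config` to write
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  y <- unclass(config)
  y$frustum <- unclass(y$frustum)
  yaml::write_yaml(y, path)
  invisible(path)
}

# Short stable hash of a config for log lines (base R only).
config_hash <- function(config) {
  s <- paste(deparse(unclass(config)), collapse = "")
  v <- utf8ToInt(s)
  h <- 5381
  for (c in v) h <- (h * 33 + c) %% 2147483647
  sprintf("%08x", as.integer(h))
}
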