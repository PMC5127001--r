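#' Pre-process all clouds of a campaign
#'
#' Applies the standard chain to every depth-camera frame (clip to the FOV
#' cross-section at the canopy top, crop to the AOI, statistical outlier
#' removal) and crops + filters the merged laser-scan reference. Returns the
#' cleaned clouds together with a retention table (points surviving each
#' stage, percent of the original cloud).
#'
#' @param campaign a `campaign` from [default_campaign]
#' @param config a `pipeline_config`
#' @return list with `singles` (list of cleaned frame `point_cloud`s),
#'   `tls` (cleaned reference cloud) and `retention` (data.frame)
#' @export
preprocess_campaign <- function(campaign, config = pipeline_config()) {
  stopifnot(inherits(campaign, "campaign"),
            inherits(config, "pipeline_config"))
  aoi <- config$aoi
  singles <- vector("list", length(campaign$k2_frames))
  rows <- vector("list", length(campaign$k2_frames) + 1)
  for (i in seq_along(campaign$k2_frames)) {
    pp <- preprocess_frame(campaign$k2_frames[[i]], campaign$k2_poses[[i]],
                           campaign$spec, campaign$top_ranges[i], aoi,
                           sor_k = config$sor_k,
                           sor_multiplier = config$sor_multiplier)
    singles[[i]] <- pp$cloud
    rows[[i]] <- cbind(data.frame(cloud = paste0("SP", i)), pp$retention)
  }
  tls0 <- campaign$tls_reference
  tls_crop <- crop_to_aoi(tls0, aoi[1], aoi[2], aoi[3], aoi[4])
  tls <- sor_filter(tls_crop, k = config$sor_k,
                    multiplier = config$sor_multiplier)$kept
  rows[[length(rows)]] <- data.frame(
    cloud = "TLS", n_original = n_points(tls0), n_fov = NA_integer_,
    n_aoi = n_points(tls_crop), n_final = n_points(tls),
    pct_retained = retention_percent(n_points(tls), n_points(tls0)))
  names(singles) <- paste0("SP", seq_along(singles))
  list(singles = singles, tls = tls, retention = do.call(rbind, rows))
}

#' Cloud variants analysed in a campaign
#'
#' The single frames plus the standard combinations: the odd frames, the
#' even frames and all frames merged.
#'
#' @param singles named list of cleaned single-frame clouds
#' @return named list of `point_cloud`s (e.g. 8 singles + `1-3-5-7`,
#'   `2-4-6-8`, `all` = 11 variants)
#' @export
cloud_variants <- function(singles) {
  n <- length(singles)
  v <- singles
  odd <- seq(1, n, by = 2)
  even <- seq(2, n, by = 2)
  v[[paste(odd, collapse = "-")]] <- merge_clouds(singles[odd])
  v[[paste(even, collapse = "-")]] <- merge_clouds(singles[even])
  v[["all"]] <- merge_clouds(singles)
  v
}

#' Full CHM accuracy assessment of a campaign
#'
#' Pre-processes the campaign, builds the reference CHM from the merged
#' laser scans and a CHM for every cloud variant (each single frame, odd
#' frames, even frames, all frames), differences each against the reference
#' and computes the robust accuracy report and the cell-level linear fit.
#'
#' @param campaign a `campaign`
#' @param config a `pipeline_config`
#' @return list with `reports` (data.frame, one row per CHM variant),
#'   `chm_sets` (named list), `ref` (reference `chm_set`), `prep` (the
#'   [preprocess_campaign] result) and `grid` (the common grid definition)
#' @export
assess_campaign <- function(campaign, config = pipeline_config()) {
  prep <- preprocess_campaign(campaign, config)
  aoi <- config$aoi
  grid <- raster_grid_def(aoi[1], aoi[2], aoi[3], aoi[4], config$cell_size)
  ref <- build_chm_set(prep$tls, grid, trim_rings = config$trim_rings)
  variants <- cloud_variants(prep$singles)
  chm_sets <- lapply(variants, build_chm_set, grid = grid,
                     trim_rings = config$trim_rings)
  rows <- lapply(names(chm_sets), function(nm) {
    diff <- difference_raster(chm_sets[[nm]]$chm, ref$chm)
    rep <- as.data.frame(accuracy_report(diff,
                                         blunder_factor = config$blunder_factor))
    fit <- cellwise_fit(chm_sets[[nm]]$chm, ref$chm)
    cbind(data.frame(chm = nm, valid_cells = valid_cells(chm_sets[[nm]]$chm)),
          rep,
          data.frame(cell_r2 = fit$r2, cell_slope = fit$slope,
                     cell_intercept = fit$intercept))
  })
  list(reports = do.call(rbind, rows), chm_sets = chm_sets, ref = ref,
       prep = prep, grid = grid)
}

#' Plant heights of a campaign compared with the ground truth
#'
#' Extracts plant heights at the known plant positions (scenario 2) from a
#' cloud and compares them with the true heights of the synthetic field.
#' Positions whose search disc holds no points are excluded from the
#' comparison (they are counted).
#'
#' @param cloud a cleaned `point_cloud` (single frame or combination)
#' @param field the `synthetic_field` ground truth
#' @param radius horizontal search radius (m)
#' @return list with `obs` (observation table incl. `true_height`),
#'   `comparison` (a `height_comparison` vs truth), `n_missing`
#' @export
heights_vs_truth <- function(cloud, field, radius = 0.125) {
  stopifnot(inherits(field, "synthetic_field"))
  obs <- heights_scenario2(cloud, field$plants, radius = radius)
  obs$true_height <- field$plants$height
  ok <- obs$n_points > 0
  list(obs = obs,
       comparison = compare_heights(obs$height[ok], obs$true_height[ok]),
       n_missing = sum(!ok))
}
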