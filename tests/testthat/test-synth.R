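test_that("field generation is reproducible and hits the layout targets", {
  f1 <- generate_field(seed = 5)
  f2 <- generate_field(seed = 5)
  f3 <- generate_field(seed = 6)
  expect_identical(f1$plants, f2$plants)
  expect_false(isTRUE(all.equal(f1$plants$x, f3$plants$x)))

  p <- f1$plants
  expect_equal(nrow(p), 52L)
  expect_true(all(p$x >= 0 & p$x <= 2.5 & p$y >= 0 & p$y <= 8))
  expect_true(all(p$height >= 0.55 - 1e-9 & p$height <= 2.41 + 1e-9))
  # height gradient follows y (south-to-north)
  expect_gt(cor(p$y, p$height), 0.9)
  # mean spacings within 5% of the configured values
  ys <- tapply(p$y, round((p$y - min(p$y)) / 0.58), mean)
  xs <- tapply(p$x, round((p$x - min(p$x)) / 0.46), mean)
  expect_equal(mean(diff(ys)), 0.58, tolerance = 0.05)
  expect_equal(mean(diff(xs)), 0.46, tolerance = 0.05)

  one <- generate_field(n_plants = 1, seed = 2)
  expect_equal(c(one$plants$x, one$plants$y), c(1.25, 4.0))
  expect_error(generate_field(n_plants = 500, spacing_long = 0.58),
               "infeasible")
})

test_that("plant apices sit exactly at the true height over terrain", {
  f <- generate_field(seed = 9)
  s <- sample_field_surface(f)
  for (id in c(1, 26, 52)) {
    sel <- s$plant_id == id
    zg <- terrain_z(f$terrain, f$plants$x[id], f$plants$y[id])
    expect_equal(max(s$xyz[sel, 3]), zg + f$plants$height[id],
                 tolerance = 1e-9)
  }
})

test_that("a bare-terrain frame returns every pixel at the pinhole range", {
  f <- generate_field(n_plants = 1, seed = 2)
  f$plants <- f$plants[0, ]  # bare terrain
  pose <- nadir_pose(0, 0, 3.75)
  fr <- render_depth_frame(f, pose, noise = noise_none(), seed = 1)
  expect_equal(n_points(fr), 217088L)
  rng <- sqrt(rowSums(sweep(fr$xyz, 2, pose$origin)^2))
  # per pixel: range = h / cos(theta) for the angle off the boresight
  cth <- (3.75 - fr$xyz[, 3]) / rng
  expect_lt(max(abs(rng - 3.75 / cth)), 1e-9)
  expect_equal(max(abs(fr$xyz[, 3])), 0, tolerance = 1e-9)
})

test_that("renders are bitwise reproducible and occlusion blocks terrain", {
  f <- generate_field(n_plants = 1, extent = c(1, 1), spacing_long = 0.5,
                      spacing_trans = 0.5, height_range = c(1.2, 1.2),
                      seed = 3)
  pose <- nadir_pose(0.5, 0.5, 3.3)
  a <- render_depth_frame(f, pose, seed = 10)
  b <- render_depth_frame(f, pose, seed = 10)
  expect_identical(a$xyz, b$xyz)

  # no terrain returns inside the silhouette of a super-pixel structure:
  # a thick stem occludes the ground directly beneath it
  ff <- f
  ff$shape <- list(stem_radius = 0.04, tip_radius = 0.035,
                   taper_length = 0.3, leaf_width = 0.045)
  nf <- render_depth_frame(ff, pose, noise = noise_none(), seed = 1)
  d2 <- (nf$xyz[, 1] - ff$plants$x)^2 + (nf$xyz[, 2] - ff$plants$y)^2
  under <- d2 < 0.02^2
  expect_gt(sum(under), 0)
  expect_true(all(nf$xyz[under, 3] > 0.05))
})

test_that("the virtual laser scanner spacing matches its angular step", {
  expect_equal(round(theoretical_spacing(5, 0.029, 1), 4), 0.0025)
  f <- generate_field(n_plants = 1, extent = c(0.5, 0.5),
                      spacing_long = 0.2, spacing_trans = 0.2,
                      height_range = c(0.6, 0.6), seed = 4)
  sc <- render_tls_scan(f, c(0.25, -3, 2), angular_resolution = 0.2,
                        range_sd = 0, seed = 1)
  expect_gt(n_points(sc), 100)
  terr <- sc$xyz[sc$attrs$surface == "terrain", ]
  expect_lt(max(abs(terr[, 3])), 1e-9)
  # plant apex is captured without a pixel-fill penalty
  plant <- sc$xyz[sc$attrs$surface == "plant", ]
  expect_equal(max(plant[, 3]), 0.6, tolerance = 0.01)
})

test_that("with noise disabled the bare-terrain CHM error is exactly zero", {
  f <- generate_field(n_plants = 1, seed = 2)
  f$plants <- f$plants[0, ]
  pose <- nadir_pose(1.25, 4, 3.0)
  fr <- render_depth_frame(f, pose, noise = noise_none(), seed = 1)
  grid <- raster_grid_def(0.5, 3, 2, 5, 0.25)
  cs <- build_chm_set(crop_to_aoi(fr, 0.5, 3, 2, 5), grid, trim_rings = 0)
  expect_true(all(cs$chm$values == 0))
})

test_that("coarser apices reduce the depth-camera height bias", {
  biases <- vapply(c(0.002, 0.006, 0.02), function(tr) {
    f <- generate_field(n_plants = 1, extent = c(1, 1),
                        spacing_long = 0.5, spacing_trans = 0.5,
                        height_range = c(1.5, 1.5), seed = 3,
                        shape = list(stem_radius = 0.012, tip_radius = tr,
                                     taper_length = 0.3,
                                     leaf_width = 0.045))
    pose <- nadir_pose(0.5, 0.5, 1.5 + 2.05)
    fr <- render_depth_frame(f, pose, noise = noise_none(), seed = 1)
    h <- heights_scenario2(fr, data.frame(x = f$plants$x, y = f$plants$y))
    abs(h$height - 1.5)
  }, numeric(1))
  expect_true(all(diff(biases) <= 1e-9))
  expect_gt(biases[1], biases[3])
})

test_that("the default campaign has the documented structure", {
  tc <- get_test_campaign()
  camp <- tc$campaign
  expect_length(camp$k2_frames, 8)
  expect_length(camp$tls_scans, 5)
  ys <- vapply(camp$k2_poses, function(p) p$origin[2], numeric(1))
  expect_true(all(diff(ys) > 0))          # poses advance along the long axis
  zs <- vapply(camp$k2_poses, function(p) p$origin[3], numeric(1))
  expect_equal(mean(zs), 3.75, tolerance = 0.15)
  expect_true(all(vapply(camp$k2_frames, n_points, integer(1)) <=
                    217088 + 0))

  # union of clipped frame footprints covers the AOI
  ht_y <- 2.05 * tan(30 * pi / 180)
  covered <- any(ys[1] - ht_y <= 0) && any(ys[8] + ht_y >= 8)
  gaps <- all(diff(ys) < 2 * ht_y)
  expect_true(covered && gaps)
})

test_that("combining frames closes coverage gaps in the rasters", {
  tc <- get_test_campaign()
  rep <- tc$assessment$reports
  singles <- rep$valid_cells[grepl("^SP", rep$chm)]
  comb <- rep$valid_cells[rep$chm == "all"]
  expect_true(all(comb >= singles))
  expect_equal(comb, 240L)  # full trimmed 10 x 32 grid

  # merged depth frames and merged laser scans both see terrain in every
  # 0.25 m cell (untrimmed DTM fully populated)
  grid <- raster_grid_def(0, 0, 2.5, 8, 0.25)
  dtm_k2 <- rasterize_extreme(tc$combined, grid, "min")
  expect_equal(valid_cells(dtm_k2), 320L)
  dtm_tls <- rasterize_extreme(tc$assessment$prep$tls, grid, "min")
  expect_equal(valid_cells(dtm_tls), 320L)
})

test_that("depth-camera CHMs sit below the laser reference on average", {
  tc <- get_test_campaign()
  rep <- tc$assessment$reports
  expect_true(all(rep$mean < 0))
  expect_true(all(rep$q50 < 0))
})

test_that("combined clouds dominate single frames for plant heights", {
  tc <- get_test_campaign()
  truth <- tc$field$plants
  comb <- heights_scenario2(tc$combined, truth)
  for (i in c(1, 4, 8)) {
    single <- heights_scenario2(tc$assessment$prep$singles[[i]], truth)
    seen <- single$n_points > 0
    # the combined cloud is a superset: max can only rise, min only fall
    expect_true(all(comb$height[seen] >= single$height[seen] - 1e-9))
  }
})

test_that("overlapping frames yield duplicate scenario-1 observations", {
  tc <- get_test_campaign()
  per_frame <- lapply(tc$assessment$prep$singles, heights_scenario1)
  all_obs <- do.call(rbind, per_frame)
  truth <- tc$field$plants
  idx <- nadirchm:::cpp_nearest_within(all_obs$x, all_obs$y,
                                       truth$x, truth$y, 0.125)
  matched <- idx[idx > 0]
  expect_gt(length(matched), length(unique(matched)))
})
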