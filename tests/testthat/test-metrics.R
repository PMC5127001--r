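test_that("NMAD matches its definition and estimates sigma", {
  expect_equal(nmad(c(3, 3, 3)), 0)
  expect_equal(nmad(1:5), 1.4826)
  set.seed(91)
  x <- rnorm(1e5, 0, 0.42)
  expect_equal(nmad(x), 0.42, tolerance = 0.02)
  expect_error(nmad(numeric(0)), "empty")
})

test_that("accuracy report handles degenerate and constant differences", {
  z <- accuracy_report(rep(0, 50))
  expect_equal(z$rmse, 0)
  expect_equal(z$mean, 0)
  expect_equal(z$nmad, 0)
  expect_true(is.na(z$qq_r2))

  k <- accuracy_report(rep(-0.06, 40))
  expect_equal(k$mean, -0.06)
  expect_equal(k$q50, -0.06)
  expect_equal(k$sd, 0)
  expect_equal(k$rmse, 0.06)
  expect_equal(k$blunder_count, 0L)
  expect_error(accuracy_report(1), "at least 2")
})

test_that("normal differences recover the closed-form quantiles", {
  set.seed(92)
  d <- rnorm(1e5)
  r <- accuracy_report(d)
  expect_equal(r$rmse, 1, tolerance = 0.02)
  expect_equal(r$sd, 1, tolerance = 0.02)
  expect_equal(r$nmad, 1, tolerance = 0.02)
  expect_equal(r$q95, qnorm(0.975), tolerance = 0.02)
  expect_equal(r$q683, 1, tolerance = 0.02)  # |N(0,1)| ~ 68.3% at 1 sigma
  expect_gt(r$qq_r2, 0.99)
})

test_that("accuracy statistics match a naive reimplementation to 1e-12", {
  for (s in 1:5) {
    set.seed(200 + s)
    d <- rnorm(1000, sd = 0.1) + c(rep(0, 990), runif(10, 1, 2))
    r <- accuracy_report(d)
    o <- oracle_accuracy(d)
    for (f in names(o))
      expect_equal(r[[f]], o[[f]], tolerance = 1e-12, label = f)
  }
})

test_that("robust measures resist blunders; RMSE and SD do not", {
  set.seed(95)
  clean <- rnorm(2000, 0, 0.05)
  dirty <- c(clean, runif(60, 1, 2))  # 3% gross blunders
  rc <- accuracy_report(clean)
  rd <- accuracy_report(dirty)
  expect_equal(rd$nmad, rc$nmad, tolerance = 0.05)
  expect_equal(rd$q50, rc$q50, tolerance = 0.01)
  expect_gt(rd$rmse, 3 * rc$rmse)
  expect_gt(rd$sd, 3 * rc$sd)
  # heavy tails: NMAD falls below the SD
  expect_lt(rd$nmad, rd$sd)
  # near-normal data: NMAD tracks the SD
  expect_equal(rc$nmad / rc$sd, 1, tolerance = 0.05)
})

test_that("cell-level fits recover exact linear relations", {
  v <- matrix(runif(60, 0, 2), 10, 6)
  v[c(2, 30)] <- NA
  ref <- raster_grid(c(0, 0), 0.25, v)
  same <- cellwise_fit(ref, ref)
  expect_equal(same$r2, 1)
  expect_equal(same$slope, 1, tolerance = 1e-9)
  expect_equal(same$intercept, 0, tolerance = 1e-9)

  lower <- raster_grid(c(0, 0), 0.25, v - 0.06)
  fit <- cellwise_fit(lower, ref)
  expect_equal(fit$r2, 1)
  expect_equal(fit$intercept, -0.06, tolerance = 1e-9)
  expect_equal(fit$n, sum(!is.na(v)))
})

test_that("plane characterization recovers injected noise and bias", {
  # noiseless plane at the exact range
  clean <- render_plane_scan(2.0, noise = noise_none(), seed = 1)
  p0 <- plane_precision_accuracy(clean, 2.0)
  expect_lt(p0$precision, 1e-9)
  expect_lt(p0$accuracy_rmse, 1e-9)

  # Gaussian range noise of 0.003 m shows up as the precision
  nm <- noise_model(sd_values = c(0.003, 0.003), bias_values = c(0, 0))
  noisy <- render_plane_scan(2.0, noise = nm, seed = 2)
  p1 <- plane_precision_accuracy(noisy, 2.0)
  expect_equal(p1$precision, 0.003, tolerance = 0.1)

  # the default sensor model reproduces the characterized performance
  for (r in c(0.8, 4.0)) {
    pc <- render_plane_scan(r, seed = 3)
    p <- plane_precision_accuracy(pc, r)
    expect_gte(p$precision, 0.0008)
    expect_lte(p$precision, 0.0033)
  }
})

test_that("artefact statistics summarize counts and face distances", {
  pose <- nadir_pose(0, 0, 5)
  spec <- frustum_spec()
  empty <- lapply(1:3, function(i) point_cloud(matrix(numeric(0), 0, 3)))
  s0 <- artefact_stats(empty, pose, spec)
  expect_equal(s0$count_mean, 0)

  # artefacts placed exactly on the far cap have zero face distance
  tx <- tan(35 * pi / 180); ty <- tan(30 * pi / 180)
  on_face <- to_world_frame(cbind(runif(50, -1, 1) * 4.5 * tx,
                                  runif(50, -1, 1) * 4.5 * ty, 4.5), pose)
  s1 <- artefact_stats(list(point_cloud(on_face)), pose, spec)
  expect_lt(s1$dist_median, 1e-9)
  expect_equal(s1$count_mean, 50)
})

test_that("reporting helpers reproduce the printed-percentage convention", {
  expect_equal(retention_percent(70430, 217088), 32.44)
  expect_equal(relative_underestimation(-0.05, 2.0), 2.5)
  expect_error(retention_percent(5, 0))
})
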