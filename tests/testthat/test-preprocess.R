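test_that("SOR removes isolated points and partitions the cloud", {
  # regular grid, k = 1: every nearest-neighbor distance equals the grid
  # step, SD = 0, and the strict inequality keeps everything
  g <- expand.grid(x = 0:9, y = 0:9)
  reg <- point_cloud(cbind(g$x, g$y, 0))
  res <- sor_filter(reg, k = 1)
  expect_equal(n_points(res$kept), 100L)
  expect_equal(n_points(res$removed), 0L)
  expect_equal(res$threshold, 1)

  # grid plus one far point: exactly the far point goes
  far <- point_cloud(rbind(cbind(g$x, g$y, 0), c(50, 50, 0)))
  res2 <- sor_filter(far, k = 5)
  expect_equal(n_points(res2$removed), 1L)
  expect_equal(res2$removed$xyz[1, ], c(x = 50, y = 50, z = 0))

  # partition property on a random cloud, and exact kNN distances
  pc <- random_cloud(400, seed = 77)
  res3 <- sor_filter(pc, k = 5)
  expect_equal(n_points(res3$kept) + n_points(res3$removed), 400L)
  expect_equal(sort(rbind(res3$kept$xyz, res3$removed$xyz)[, 1]),
               sort(pc$xyz[, 1]))
  expect_equal(res3$mean_dist, oracle_knn_mean_dist(pc$xyz, 5),
               tolerance = 1e-12)

  expect_error(sor_filter(subset_cloud(pc, 1:5), k = 5), "more than k")
})

test_that("the literal sd-only SOR rule is available and more aggressive", {
  pc <- random_cloud(500, seed = 13, box = c(0.5, 0.5, 0.5))
  a <- sor_filter(pc, k = 5, rule = "mean_sd")
  b <- sor_filter(pc, k = 5, rule = "sd_only")
  expect_gte(b$n_removed, a$n_removed)
})

test_that("tie-point registration recovers exact and noisy transforms", {
  # identity and pure translation
  set.seed(41)
  src <- matrix(runif(30), ncol = 3)
  ident <- rigid_from_tiepoints(src, src)
  expect_lt(max(abs(ident$transform$rotation - diag(3))), 1e-12)
  expect_equal(ident$residual_sd, 0, tolerance = 1e-12)

  shift <- rigid_from_tiepoints(src, sweep(src, 2, c(1, -2, 0.5), `+`))
  expect_lt(max(abs(shift$transform$rotation - diag(3))), 1e-9)
  expect_equal(shift$transform$translation, c(1, -2, 0.5),
               tolerance = 1e-9)

  # random rotation + translation, exact pairs
  ax <- c(0.3, -0.5, 0.8); ax <- ax / sqrt(sum(ax^2)); th <- 1.1
  K <- matrix(c(0, ax[3], -ax[2], -ax[3], 0, ax[1], ax[2], -ax[1], 0), 3, 3)
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
  t <- c(4, -1, 2)
  tgt <- sweep(src %*% t(R), 2, t, `+`)
  fit <- rigid_from_tiepoints(src, tgt)
  expect_lt(max(abs(fit$transform$rotation - R)), 1e-9)
  expect_lt(max(abs(fit$transform$translation - t)), 1e-9)

  # with isotropic noise the residual RMSE tracks sigma * sqrt(3)
  set.seed(42)
  n <- 50; sig <- 0.004
  src2 <- matrix(runif(3 * n), ncol = 3)
  tgt2 <- sweep(src2 %*% t(R), 2, t, `+`) + matrix(rnorm(3 * n, 0, sig),
                                                   ncol = 3)
  fit2 <- rigid_from_tiepoints(src2, tgt2)
  expect_equal(fit2$rmse, sig * sqrt(3), tolerance = 0.2)

  # invariant to relabeling pair order
  perm <- sample(n)
  fit3 <- rigid_from_tiepoints(src2[perm, ], tgt2[perm, ])
  expect_equal(fit3$transform$rotation, fit2$transform$rotation,
               tolerance = 1e-12)
  expect_equal(sort(fit3$residuals), sort(fit2$residuals),
               tolerance = 1e-12)

  expect_error(rigid_from_tiepoints(cbind(1:5, 1:5, 1:5),
                                    cbind(2:6, 2:6, 2:6)), "degenerate")
})

test_that("tie-point rotation agrees with an independent Procrustes fit", {
  skip_if_not_installed("vegan")
  set.seed(53)
  src <- matrix(runif(36), ncol = 3)
  ax <- c(1, 2, -1); ax <- ax / sqrt(sum(ax^2)); th <- 0.7
  K <- matrix(c(0, ax[3], -ax[2], -ax[3], 0, ax[1], ax[2], -ax[1], 0), 3, 3)
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
  tgt <- sweep(src %*% t(R), 2, c(0.5, 0, -1), `+`) +
    matrix(rnorm(36, 0, 0.01), ncol = 3)
  fit <- rigid_from_tiepoints(src, tgt)
  pr <- vegan::procrustes(tgt, src, scale = FALSE)
  expect_lt(max(abs(fit$transform$rotation - t(pr$rotation))), 1e-6)
})

test_that("merging and AOI cropping behave like the box oracle", {
  a <- random_cloud(120, seed = 1)
  b <- random_cloud(80, seed = 2, origin = c(5, 5, 0))
  m <- merge_clouds(list(a = a, b = b))
  expect_equal(n_points(m), 200L)
  expect_equal(as.integer(table(m$attrs$source)[c("a", "b")]),
               c(120L, 80L))
  expect_identical(merge_clouds(list(a))$xyz, a$xyz)
  expect_error(merge_clouds(list()), "non-empty")

  pc <- random_cloud(500, seed = 3, box = c(4, 4, 1), origin = c(-1, -1, 0))
  cr <- crop_to_aoi(pc, 0, 0, 2, 2)
  keep <- pc$xyz[, 1] >= 0 & pc$xyz[, 1] <= 2 &
    pc$xyz[, 2] >= 0 & pc$xyz[, 2] <= 2
  expect_equal(cr$xyz, pc$xyz[keep, , drop = FALSE])
  edge <- point_cloud(rbind(c(0, 1, 0), c(2, 2, 0), c(2.0001, 1, 0)))
  expect_equal(n_points(crop_to_aoi(edge, 0, 0, 2, 2)), 2L)
  expect_error(crop_to_aoi(pc, 2, 0, 0, 2), "inverted")
})

test_that("tie points round-trip through the 6-column CSV format", {
  tp <- data.frame(xs = runif(5), ys = runif(5), zs = runif(5),
                   xt = runif(5), yt = runif(5), zt = runif(5))
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(tp, path, row.names = FALSE)
  got <- read_tiepoints(path)
  expect_equal(unname(got$source), unname(as.matrix(tp[, 1:3])))
  expect_equal(unname(got$target), unname(as.matrix(tp[, 4:6])))
  bad <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(a = 1), bad, row.names = FALSE)
  expect_error(read_tiepoints(bad), "columns")
})
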