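test_that("theoretical spacing matches the closed form and is monotone", {
  expect_equal(theoretical_spacing(0.5, 70, 512),
               2 * 0.5 * tan(35 * pi / 180) / 512)
  r <- seq(0.5, 4.5, by = 0.5)
  s <- theoretical_spacing(r, 70, 512)
  expect_true(all(diff(s) > 0))
  expect_true(all(theoretical_spacing(2, 70, c(128, 256, 512)) ==
                    sort(theoretical_spacing(2, 70, c(128, 256, 512)),
                         decreasing = TRUE)))
  expect_error(theoretical_spacing(0, 70, 512), "positive")
  expect_error(theoretical_spacing(1, 70, 0), "n_pixels")
  expect_error(theoretical_spacing(1, 190, 512), "full_angle")
})

test_that("frustum membership agrees with the half-space oracle", {
  spec <- frustum_spec()
  pose <- nadir_pose(0.3, -0.2, 4.0, yaw = 25)
  # boresight point at mid-range is inside; a point behind is not
  mid <- pose$origin + as.vector(pose$rotation %*% c(0, 0, 2.5))
  behind <- pose$origin + as.vector(pose$rotation %*% c(0, 0, -1))
  expect_true(frustum_contains(rbind(mid), pose, spec))
  expect_false(frustum_contains(rbind(behind), pose, spec))

  set.seed(11)
  xyz <- cbind(runif(1000, -6, 6), runif(1000, -6, 6), runif(1000, -2, 6))
  expect_identical(unname(frustum_contains(xyz, pose, spec)),
                   unname(oracle_frustum_contains(xyz, pose, spec)))
})

test_that("top-FOV clipping matches the rectangle oracle and is idempotent", {
  spec <- frustum_spec()
  pose <- nadir_pose(1.0, 2.0, 3.75)
  pc <- random_cloud(2000, seed = 5, box = c(6, 6, 3.7),
                     origin = c(-2, -1, 0))
  top <- 2.0
  clipped <- clip_to_top_fov(pc, pose, spec, top)

  s <- to_sensor_frame(pc$xyz, pose)
  keep <- abs(s[, 1]) <= top * tan(35 * pi / 180) &
    abs(s[, 2]) <= top * tan(30 * pi / 180)
  expect_equal(clipped$xyz, pc$xyz[keep, , drop = FALSE])

  again <- clip_to_top_fov(clipped, pose, spec, top)
  expect_identical(again$xyz, clipped$xyz)

  below <- nadir_pose(0, 0, 3)
  directly_under <- point_cloud(rbind(c(0, 0, 1)))
  expect_equal(n_points(clip_to_top_fov(directly_under, below, spec, 1.0)), 1L)
  expect_error(clip_to_top_fov(pc, pose, spec, 10), "top_range")
})

test_that("rigid transforms compose, invert and round-trip to 1e-9", {
  set.seed(3)
  th <- runif(3, -pi, pi)
  Rx <- matrix(c(1, 0, 0, 0, cos(th[1]), sin(th[1]),
                 0, -sin(th[1]), cos(th[1])), 3, 3)
  Rz <- matrix(c(cos(th[2]), sin(th[2]), 0, -cos(th[2]) * 0 - sin(th[2]),
                 cos(th[2]), 0, 0, 0, 1), 3, 3)
  tr <- rigid_transform(Rx %*% Rz, c(0.4, -2, 1.1))
  xyz <- matrix(rnorm(300), ncol = 3)
  back <- apply_transform(invert_transform(tr), apply_transform(tr, xyz))
  expect_lt(max(abs(back - xyz)), 1e-9)

  comp <- compose_transforms(invert_transform(tr), tr)
  expect_lt(max(abs(comp$rotation - diag(3))), 1e-9)
  expect_lt(max(abs(comp$translation)), 1e-9)
  expect_error(rigid_transform(diag(c(1, 1, -1)), c(0, 0, 0)), "determinant")
})

test_that("RANSAC plane fitting is robust and recovers noise scale", {
  # exact horizontal plane
  pc <- random_cloud(200, seed = 9, box = c(2, 2, 0))
  pc$xyz[, 3] <- 1
  pm <- fit_plane_ransac(pc, seed = 4)
  expect_equal(abs(pm$normal), c(0, 0, 1), tolerance = 1e-12)
  expect_equal(pm$offset, 1, tolerance = 1e-12)
  expect_true(all(pm$inliers))

  # 10% gross outliers are excluded from the consensus set
  set.seed(21)
  n <- 500
  base <- cbind(runif(n), runif(n), 0.5 + rnorm(n, 0, 0.002))
  out_idx <- sample(n, 50)
  base[out_idx, 3] <- base[out_idx, 3] + runif(50, 0.3, 1.5)
  pm2 <- fit_plane_ransac(point_cloud(base), dist_threshold = 0.01,
                          seed = 8)
  expect_true(all(!pm2$inliers[out_idx]))
  expect_gt(mean(pm2$inliers[-out_idx]), 0.99)

  # residual SD recovers injected sigma within 10%
  set.seed(22)
  sig <- 0.005
  m <- cbind(runif(1e4, 0, 2), runif(1e4, 0, 2), rnorm(1e4, 0, sig))
  pm3 <- fit_plane_ransac(point_cloud(m), dist_threshold = 0.05, seed = 2)
  expect_equal(sd(pm3$residuals[pm3$inliers]), sig, tolerance = 0.1)

  collinear <- point_cloud(cbind(1:5, 1:5, 1:5))
  expect_error(fit_plane_ransac(collinear, seed = 1), "degenerate")
})

test_that("frustum face distances match closed forms and a mesh oracle", {
  spec <- frustum_spec()
  pose <- nadir_pose(0, 0, 5)
  tx <- tan(35 * pi / 180)
  ty <- tan(30 * pi / 180)

  # a point exactly on the +x side face (sensor frame), world coords
  s_face <- c(2 * tx, 0, 2)
  w_face <- to_world_frame(rbind(s_face), pose)
  expect_equal(frustum_face_distances(w_face, pose, spec), 0,
               tolerance = 1e-9)

  # boresight mid-range: nearest face is a side plane; distance is the
  # point-plane distance to it
  smid <- c(0, 0, 2.5)
  wmid <- to_world_frame(rbind(smid), pose)
  d_side_y <- 2.5 * ty / sqrt(1 + ty^2)   # distance to the y side plane
  d_caps <- min(2.5 - spec$min_range, spec$max_range - 2.5)
  expect_equal(frustum_face_distances(wmid, pose, spec)[1],
               min(d_side_y, d_caps), tolerance = 1e-9)

  # brute-force oracle: dense sampling of the boundary surface
  mesh_pts <- local({
    zs <- seq(spec$min_range, spec$max_range, length.out = 160)
    side <- do.call(rbind, lapply(zs, function(z) {
      xs <- seq(-z * tx, z * tx, length.out = 60)
      ys <- seq(-z * ty, z * ty, length.out = 60)
      rbind(cbind(xs, -z * ty, z), cbind(xs, z * ty, z),
            cbind(-z * tx, ys, z), cbind(z * tx, ys, z))
    }))
    caps <- do.call(rbind, lapply(c(spec$min_range, spec$max_range),
                                  function(z) {
      g <- expand.grid(x = seq(-z * tx, z * tx, length.out = 60),
                       y = seq(-z * ty, z * ty, length.out = 60))
      cbind(g$x, g$y, z)
    }))
    to_world_frame(rbind(side, caps), pose)
  })
  set.seed(31)
  test_s <- cbind(runif(40, -2, 2), runif(40, -2, 2), runif(40, 0.2, 5))
  test_w <- to_world_frame(test_s, pose)
  got <- frustum_face_distances(test_w, pose, spec)
  brute <- apply(test_w, 1, function(p)
    sqrt(min(colSums((t(mesh_pts) - p)^2))))
  # the sampled-boundary oracle overestimates by at most its grid spacing
  expect_true(all(brute - got >= -1e-9))
  expect_lt(max(abs(got - brute)), 0.06)
})
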