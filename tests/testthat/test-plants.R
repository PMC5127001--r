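test_that("local maxima selection is strict with index tie-break", {
  single <- point_cloud(rbind(c(0, 0, 1)))
  expect_equal(n_points(find_local_maxima(single)), 1L)

  two <- point_cloud(rbind(c(0, 0, 1), c(0.05, 0, 2)))
  mx <- find_local_maxima(two, radius = 0.125)
  expect_equal(unname(mx$xyz[, 3]), 2)

  tie <- point_cloud(rbind(c(0, 0, 1), c(0.01, 0, 1)))
  mx2 <- find_local_maxima(tie, radius = 0.125)
  expect_equal(n_points(mx2), 1L)
  expect_equal(mx2$xyz[1, 1:2], c(x = 0, y = 0))

  # well-separated peaks: one maximum per peak
  set.seed(61)
  centers <- expand.grid(x = seq(0.5, 2, by = 0.5),
                         y = seq(0.5, 3.5, by = 0.5))
  pts <- do.call(rbind, lapply(seq_len(nrow(centers)), function(i) {
    ang <- runif(30, 0, 2 * pi); rr <- runif(30, 0.01, 0.05)
    cbind(centers$x[i] + rr * cos(ang), centers$y[i] + rr * sin(ang),
          runif(30, 0, 0.8 + 0.01 * i))
  }))
  mx3 <- find_local_maxima(point_cloud(pts), radius = 0.125)
  expect_equal(n_points(mx3), nrow(centers))
})

test_that("scenario-1 heights use disc minima and the 0.5 m floor", {
  ground <- expand.grid(x = seq(-0.1, 0.1, by = 0.02),
                        y = seq(-0.1, 0.1, by = 0.02))
  column <- cbind(0, 0, seq(0, 1.2, by = 0.05))
  pc <- point_cloud(rbind(cbind(ground$x, ground$y, 0), column))
  obs <- heights_scenario1(pc)
  expect_equal(nrow(obs), 1L)
  expect_equal(obs$height, 1.2)
  expect_equal(obs$z_min, 0)

  short <- point_cloud(rbind(cbind(ground$x, ground$y, 0),
                             cbind(0, 0, seq(0, 0.4, by = 0.05))))
  expect_equal(nrow(heights_scenario1(short)), 0L)
})

test_that("scenario-2 heights equal a brute-force disc scan", {
  pos <- data.frame(id = 1:3, x = c(0.3, 1.1, 2.0), y = c(0.4, 0.9, 3.0))
  pc <- random_cloud(600, seed = 8, box = c(2.5, 4, 2))
  obs <- heights_scenario2(pc, pos, radius = 0.125)
  for (i in 1:3) {
    d2 <- (pc$xyz[, 1] - pos$x[i])^2 + (pc$xyz[, 2] - pos$y[i])^2
    inside <- d2 <= 0.125^2
    expect_equal(obs$z_max[i], max(pc$xyz[inside, 3]))
    expect_equal(obs$z_min[i], min(pc$xyz[inside, 3]))
    expect_equal(obs$n_points[i], sum(inside))
  }
  # a position over a single point yields height zero
  one <- heights_scenario2(point_cloud(rbind(c(0, 0, 0.7))),
                           data.frame(x = 0, y = 0))
  expect_equal(one$height, 0)
  # empty disc is reported as missing, not dropped
  far <- heights_scenario2(pc, data.frame(x = 50, y = 50))
  expect_equal(nrow(far), 1L)
  expect_true(is.na(far$height))
  expect_equal(far$n_points, 0L)
})

test_that("reference matching drops observations beyond the radius", {
  set.seed(71)
  base <- rbind(cbind(runif(200, 0, 1), runif(200, 0, 1), runif(200, 0, 0.1)),
                c(0.5, 0.5, 1.5))
  pc <- point_cloud(base)
  obs <- heights_scenario1(pc)
  self <- match_to_reference(obs, pc)
  expect_equal(nrow(self$pairs), nrow(obs))
  expect_equal(self$pairs$height, self$pairs$ref_height)
  expect_equal(self$n_unmatched, 0L)

  # a reference whose only local maximum is displaced beyond the radius
  lone <- data.frame(id = 1, x = 0.5, y = 0.5, z_max = 1.5, z_min = 0,
                     height = 1.5, source = "scenario1")
  ref <- point_cloud(cbind(0.9, 0.5, seq(0, 1.4, by = 0.1)))
  moved <- match_to_reference(lone, ref)
  expect_equal(nrow(moved$pairs), 0L)
  expect_equal(moved$n_unmatched, 1L)
})

test_that("height comparison statistics behave on constructed pairs", {
  h <- seq(0.6, 2.4, length.out = 30)
  same <- compare_heights(h, h)
  expect_equal(same$r2, 1)
  expect_equal(same$rmse_diff, 0)

  off <- compare_heights(h - 0.06, h)
  expect_equal(off$r2, 1)
  expect_equal(off$median_diff, -0.06)
  expect_equal(off$sd_diff, 0)
  expect_equal(off$intercept, -0.06, tolerance = 1e-9)

  set.seed(81)
  sig <- 0.05
  noisy <- compare_heights(h2 <- rep(h, length.out = 100) +
                             rnorm(100, 0, sig), rep(h, length.out = 100))
  expect_equal(noisy$rmse_diff, sig, tolerance = 0.15)
  expect_error(compare_heights(1, 1), "at least 2")
})
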