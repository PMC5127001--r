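# Independent brute-force oracles and shared fixtures for the suite.

random_cloud <- function(n, seed, box = c(1, 1, 1), origin = c(0, 0, 0)) {
  set.seed(seed)
  point_cloud(cbind(origin[1] + runif(n) * box[1],
                    origin[2] + runif(n) * box[2],
                    origin[3] + runif(n) * box[3]))
}

# O(n^2) exact mean k-nearest-neighbor distances.
oracle_knn_mean_dist <- function(xyz, k) {
  D <- as.matrix(stats::dist(xyz))
  diag(D) <- Inf
  unname(apply(D, 1, function(r) mean(sort(r)[seq_len(k)])))
}

# Frustum membership from the raw half-space inequalities, written against
# the pose's rotation columns directly (no shared code with the package).
oracle_frustum_contains <- function(xyz, pose, spec) {
  R <- pose$rotation
  o <- pose$origin
  tx <- tan(spec$h_fov * pi / 360)
  ty <- tan(spec$v_fov * pi / 360)
  apply(xyz, 1, function(p) {
    d <- p - o
    x <- sum(d * R[, 1]); y <- sum(d * R[, 2]); z <- sum(d * R[, 3])
    z >= spec$min_range && z <= spec$max_range &&
      x <= z * tx && -x <= z * tx && y <= z * ty && -y <= z * ty
  })
}

# Per-cell extreme by explicit group-by loop.
oracle_rasterize <- function(xyz, origin, cell_size, nr, nc, mode) {
  v <- matrix(NA_real_, nr, nc)
  for (p in seq_len(nrow(xyz))) {
    j <- floor((xyz[p, 1] - origin[1]) / cell_size) + 1
    i <- floor((xyz[p, 2] - origin[2]) / cell_size) + 1
    if (xyz[p, 1] == origin[1] + nc * cell_size) j <- nc
    if (xyz[p, 2] == origin[2] + nr * cell_size) i <- nr
    if (i < 1 || i > nr || j < 1 || j > nc) next
    z <- xyz[p, 3]
    cur <- v[i, j]
    v[i, j] <- if (is.na(cur)) z
               else if (mode == "max") max(cur, z) else min(cur, z)
  }
  v
}

# Naive reimplementation of the accuracy measures.
oracle_accuracy <- function(d, blunder_factor = 3) {
  d <- d[!is.na(d)]
  rmse <- sqrt(sum(d^2) / length(d))
  bl <- abs(d) > blunder_factor * rmse
  md <- sort(d)[c(floor((length(d) + 1) / 2), ceiling((length(d) + 1) / 2))]
  med <- mean(md)
  list(rmse = rmse,
       mean = sum(d) / length(d),
       sd = sqrt(sum((d - mean(d))^2) / (length(d) - 1)),
       blunder_count = sum(bl),
       mean_no_blunder = mean(d[!bl]),
       q50 = med,
       q683 = unname(quantile(abs(d), 0.683, type = 7)),
       q95 = unname(quantile(abs(d), 0.95, type = 7)),
       nmad = 1.4826 * median(abs(d - median(d))))
}

# The default synthetic campaign is expensive; build it once per test run.
.campaign_cache <- new.env(parent = emptyenv())

get_test_campaign <- function() {
  if (is.null(.campaign_cache$res)) {
    field <- generate_field(seed = 42)
    camp <- default_campaign(field, seed = 7)
    config <- pipeline_config()
    assessment <- assess_campaign(camp, config)
    combined <- merge_clouds(assessment$prep$singles)
    .campaign_cache$res <- list(field = field, campaign = camp,
                                config = config, assessment = assessment,
                                combined = combined)
  }
  .campaign_cache$res
}
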