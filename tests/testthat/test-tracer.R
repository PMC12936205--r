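px_nm <- 41.6

test_that("tracer initialization is uniform in the annulus and seeded", {
  g <- flat_geometry()
  tr <- init_tracers(100, g, seed = 3)
  expect_equal(nrow(tr), 100)
  r <- synaptrack:::radial_dist(tr$x, tr$y, g$center)
  expect_true(all(r >= g$csmac_radius & r <= g$cell_radius))
  expect_identical(tr, init_tracers(100, g, seed = 3))
  expect_error(init_tracers(0, g), "at least 1")
})

test_that("mode-1 coupling respects the 300 nm scan radius", {
  g <- flat_geometry()
  tr <- data.frame(tracer = 1, x = g$center[1] + 25, y = g$center[2],
                   state = "free")
  near <- data.frame(x = tr$x + 100 / px_nm, y = tr$y)   # 100 nm away
  far <- data.frame(x = tr$x + 400 / px_nm, y = tr$y)    # 400 nm away
  s1 <- step_mode1(tr, near, g, dt = 1, pixel_size = px_nm)
  expect_equal(s1$state, "wave_coupled")
  expect_gt(synaptrack:::radial_dist(s1$x, s1$y, g$center), 25)
  s2 <- step_mode1(tr, far, g, dt = 1, pixel_size = px_nm)
  expect_equal(s2$state, "free")
  expect_lt(synaptrack:::radial_dist(s2$x, s2$y, g$center), 25)
})

test_that("pure retrograde kinematics move tracers inward at 50 nm/s", {
  g <- flat_geometry()
  traj <- run_simulation(1, rep(list(NULL), 10), g, n_steps = 10, dt = 1,
                         pixel_size = px_nm, n = 30, seed = 5)
  r0 <- synaptrack:::radial_dist(traj$x[traj$step == 0],
                                 traj$y[traj$step == 0], g$center)
  r10 <- synaptrack:::radial_dist(traj$x[traj$step == 10],
                                  traj$y[traj$step == 10], g$center)
  expected <- pmax(r0 - 10 * 50 / px_nm, g$csmac_radius)
  expect_equal(r10, expected, tolerance = 1e-9)
})

test_that("mode 2 with an unreachable threshold equals the retrograde limit", {
  g <- flat_geometry()
  set.seed(9)
  field <- data.frame(x = runif(50, 10, 90), y = runif(50, 10, 90),
                      u = rnorm(50, 0, 20), v = rnorm(50, 0, 20))
  m2 <- run_simulation(2, list(field)[rep(1, 8)], g, n_steps = 8, dt = 1,
                       pixel_size = px_nm, n = 25, seed = 4,
                       speed_threshold = Inf)
  m1 <- run_simulation(1, rep(list(NULL), 8), g, n_steps = 8, dt = 1,
                       pixel_size = px_nm, n = 25, seed = 4)
  expect_equal(m2[, c("x", "y")], m1[, c("x", "y")], tolerance = 1e-12)
})

test_that("a uniform outward field above threshold advects all tracers outward", {
  g <- flat_geometry()
  xs <- seq(8, 88, by = 8)
  grid <- expand.grid(x = xs, y = xs)
  dx <- grid$x - g$center[1]; dy <- grid$y - g$center[2]
  rn <- pmax(sqrt(dx^2 + dy^2), 1e-9)
  field <- data.frame(x = grid$x, y = grid$y,
                      u = 40 * dx / rn, v = 40 * dy / rn)
  tr0 <- init_tracers(20, g, seed = 2)
  tr1 <- step_mode2(tr0, field, g, dt = 1, pixel_size = px_nm,
                    speed_threshold = 13)
  r0 <- synaptrack:::radial_dist(tr0$x, tr0$y, g$center)
  r1 <- synaptrack:::radial_dist(tr1$x, tr1$y, g$center)
  moved <- r0 < g$cell_radius - 2
  expect_true(all(r1[moved] > r0[moved]))
  expect_true(all(tr1$state[moved] == "flow_coupled"))
})

test_that("simulations conserve tracers, stay in bounds and are reproducible", {
  fix <- cached("coloc_movie", {
    p <- make_profile("primary", list(seed = 6, n_frames = 80))
    gt <- simulate_ground_truth(p)
    list(gt = gt, movie = render_movie(gt, p))
  })
  gt <- fix$gt
  edges <- lapply(1:40, function(t) gt_wavefront_edges(gt, t))
  traj <- run_simulation(1, edges, gt$geometry, n_steps = 40, dt = 1,
                         pixel_size = px_nm, n = 50, seed = 12)
  expect_equal(length(unique(traj$tracer)), 50)
  expect_true(all(table(traj$step) == 50))
  r <- synaptrack:::radial_dist(traj$x, traj$y, gt$geometry$center)
  expect_true(all(r >= gt$geometry$csmac_radius - 1e-9))
  expect_true(all(r <= gt$geometry$cell_radius + 1e-9))
  expect_gt(sum(traj$state == "wave_coupled"), 0)
  rerun <- run_simulation(1, edges, gt$geometry, n_steps = 40, dt = 1,
                          pixel_size = px_nm, n = 50, seed = 12)
  expect_identical(traj, rerun)
})

test_that("run-time distributions capture pure and alternating motion", {
  g <- flat_geometry()
  retro <- run_simulation(1, rep(list(NULL), 12), g, n_steps = 12, dt = 1,
                          pixel_size = px_nm, n = 10, seed = 3)
  d <- outward_time_distribution(retro, g)
  expect_null(d$outward)
  # tracers that never hit the cSMAC boundary make one 12-step inward run
  expect_equal(max(d$inward$durations), 12)
  # alternating radial steps: all runs have unit duration
  r <- 20 + rep(c(0, 1), 10)
  alt <- data.frame(tracer = 1, step = seq_along(r),
                    x = g$center[1] + r, y = g$center[2])
  da <- outward_time_distribution(alt, g)
  expect_true(all(da$outward$durations == 1))
  expect_true(all(da$inward$durations == 1))
})

test_that("duration densities normalize exactly and the KDE is non-negative", {
  set.seed(5)
  for (i in 1:5) {
    d <- duration_distribution(sample(1:12, 40, replace = TRUE), dt = 1)
    w <- diff(d$bin_edges)
    expect_equal(sum(d$density * w), 1, tolerance = 1e-9)
    expect_true(all(d$kde >= 0))
  }
})

test_that("distribution MSE is a symmetric premetric", {
  set.seed(6)
  d1 <- duration_distribution(rpois(60, 5) + 1)
  d2 <- duration_distribution(rpois(60, 9) + 1)
  expect_equal(distribution_mse(d1, d1), 0)
  expect_equal(distribution_mse(d1, d2), distribution_mse(d2, d1))
  expect_gt(distribution_mse(d1, d2), 0)
  expect_error(distribution_mse(d1, NULL), "non-empty")
})

test_that("wavefront-coupled tracers match the cluster reference better than a control", {
  fix <- cached("coloc_movie", {
    p <- make_profile("primary", list(seed = 6, n_frames = 80))
    gt <- simulate_ground_truth(p)
    list(gt = gt, movie = render_movie(gt, p))
  })
  gt <- fix$gt
  coupled_ids <- gt$labels$cluster[gt$labels$ever_coupled]
  ref <- outward_time_distribution(
    gt$clusters[gt$clusters$cluster %in% coupled_ids, ],
    gt$geometry)$outward
  edges <- lapply(1:79, function(t) gt_wavefront_edges(gt, t))
  m1 <- run_simulation(1, edges, gt$geometry, n_steps = 79, dt = 1,
                       pixel_size = px_nm, n = 100, seed = 7)
  d1 <- outward_time_distribution(m1, gt$geometry)$outward
  ctrl <- run_simulation(1, rep(list(NULL), 79), gt$geometry, n_steps = 79,
                         dt = 1, pixel_size = px_nm, n = 100, seed = 7,
                         jitter_sd = 30)
  dc <- outward_time_distribution(ctrl, gt$geometry)$outward
  expect_lt(distribution_mse(d1, ref), distribution_mse(dc, ref))
})

test_that("mode-2 speed thresholds in the 13-33 nm/s range fit best", {
  fix <- cached("coloc_movie", {
    p <- make_profile("primary", list(seed = 6, n_frames = 80))
    gt <- simulate_ground_truth(p)
    list(gt = gt, movie = render_movie(gt, p))
  })
  gt <- fix$gt
  g <- gt$geometry
  coupled_ids <- gt$labels$cluster[gt$labels$ever_coupled]
  ref <- outward_time_distribution(
    gt$clusters[gt$clusters$cluster %in% coupled_ids, ], g)$outward
  # PIV-like field: the true flow sampled on an 8-px grid with local
  # neighbourhood mixing (weak ambiguous vectors at band boundaries), a
  # log-normal magnitude spread, measurement noise and stagnant patches
  xs <- seq(9, dim(g$mask)[2] - 8, by = 8)
  grid <- expand.grid(x = xs, y = xs)
  inm <- g$mask[cbind(grid$y, grid$x)]
  grid <- grid[inm, ]
  set.seed(17)
  fields <- lapply(1:60, function(t) {
    acc_u <- acc_v <- 0
    for (ox in c(-2, 0, 2)) for (oy in c(-2, 0, 2)) {
      v <- gt$flow(grid$x + ox, grid$y + oy, t)
      acc_u <- acc_u + v[, 1]; acc_v <- acc_v + v[, 2]
    }
    sc <- exp(rnorm(nrow(grid), 0, 0.25))
    u <- acc_u / 9 * sc + rnorm(nrow(grid), 0, 2.5)
    v2 <- acc_v / 9 * sc + rnorm(nrow(grid), 0, 2.5)
    junk <- runif(nrow(grid)) < 0.15   # stagnant low-magnitude patches
    u[junk] <- rnorm(sum(junk), 0, 6)
    v2[junk] <- rnorm(sum(junk), 0, 6)
    data.frame(x = grid$x, y = grid$y, u = u, v = v2)
  })
  mse <- vapply(c(5, 13, 23, 33, 60), function(th) {
    traj <- run_simulation(2, fields, g, n_steps = 60, dt = 1,
                           pixel_size = px_nm, n = 100, seed = 8,
                           speed_threshold = th)
    d <- outward_time_distribution(traj, g)$outward
    if (is.null(d)) Inf else distribution_mse(d, ref)
  }, numeric(1))
  expect_true(which.min(mse) %in% 2:4)
})
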