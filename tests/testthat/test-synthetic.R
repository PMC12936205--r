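test_that("identical profile and seed give bit-identical ground truth and movies", {
  p <- tiny_profile(n_frames = 15)
  gt1 <- simulate_ground_truth(p)
  gt2 <- simulate_ground_truth(p)
  expect_identical(gt1$clusters, gt2$clusters)
  expect_identical(gt1$fronts, gt2$fronts)
  m1 <- render_movie(gt1, p)
  m2 <- render_movie(gt2, p)
  expect_identical(m1$tcr$frames, m2$tcr$frames)
  expect_identical(m1$actin$frames, m2$actin$frames)
})

test_that("jurkat scenarios contain no wavefronts", {
  gt <- tiny_gt("jurkat")
  expect_equal(nrow(gt$fronts), 0)
})

test_that("wavefront radius is monotone non-decreasing for every front", {
  gt <- tiny_gt("primary", wave_nucleation_rate = 0.5)
  expect_gt(nrow(gt$fronts), 0)
  for (d in split(gt$fronts, gt$fronts$front)) {
    d <- d[order(d$frame), ]
    expect_true(all(diff(d$r_edge) >= 0))
  }
})

test_that("cluster positions stay inside the cell disc", {
  gt <- tiny_gt("primary")
  r <- synaptrack:::radial_dist(gt$clusters$x, gt$clusters$y,
                                gt$geometry$center)
  expect_true(all(r <= gt$geometry$cell_radius + 1e-9))
})

test_that("without coupling, jitter or diffusion every cluster moves inward", {
  gt <- tiny_gt("primary", coupling_prob = 0, jitter_sd = 0,
                diffusive_fraction = 0, wave_nucleation_rate = 0)
  lab <- gt$labels[gt$labels$n_frames >= 2, ]
  expect_true(all(lab$r_end < lab$r_start))
  expect_true(all(lab$direction == "retrograde"))
})

test_that("realized drift speeds match the programmed retrograde speed", {
  p <- tiny_profile(jitter_sd = 0, diffusive_fraction = 0,
                    wave_nucleation_rate = 0, coupling_prob = 0,
                    cluster_lifetime = 1e6)
  gt <- simulate_ground_truth(p)
  sp <- split(gt$clusters, gt$clusters$cluster)
  speeds <- vapply(sp, function(d) {
    d <- d[order(d$frame), ]
    if (nrow(d) < 5) return(NA_real_)
    mean(sqrt(diff(d$x)^2 + diff(d$y)^2)) * p$pixel_size / p$frame_interval
  }, numeric(1))
  speeds <- speeds[!is.na(speeds)]
  expect_lt(abs(mean(speeds) - p$retro_speed), 2 * p$retro_speed_sd)
  expect_true(all(abs(speeds - p$retro_speed) <= 4 * p$retro_speed_sd))
})

test_that("empty ground truth renders a dark TCR channel", {
  p <- tiny_profile(n_clusters = 0, background_rate = 0, read_noise_sd = 0,
                    n_frames = 5)
  gt <- simulate_ground_truth(p)
  mov <- render_movie(gt, p)
  expect_true(all(mov$tcr$frames == 0))
})

test_that("a single noiseless cluster renders with its peak at the true position", {
  p <- tiny_profile(n_clusters = 1, background_rate = 0, n_frames = 5,
                    diffusive_fraction = 0, wave_nucleation_rate = 0)
  gt <- simulate_ground_truth(p)
  mov <- render_movie(gt, p, noise = FALSE)
  for (t in c(1, 3, 5)) {
    fr <- mov$tcr$frames[, , t]
    pk <- which(fr == max(fr), arr.ind = TRUE)[1, ]
    truth <- gt$clusters[gt$clusters$frame == t, ]
    expect_lt(max(abs(c(pk[2], pk[1]) - c(truth$x, truth$y))), 1)
  }
})

test_that("the actin channel is dimmed inside the cSMAC", {
  fix <- tiny_movie("primary")
  g <- fix$gt$geometry
  avg <- apply(fix$movie$actin$frames, c(1, 2), mean)
  r <- synaptrack:::pixel_radii(nrow(avg), ncol(avg), g$center)
  csmac_mean <- mean(avg[r < 0.8 * g$csmac_radius])
  lamella_mean <- mean(avg[r > 1.5 * g$csmac_radius & r < 0.9 * g$cell_radius])
  expect_lt(csmac_mean, 0.5 * lamella_mean)
})

test_that("image stacks round-trip through multi-page TIFF with metadata", {
  fix <- tiny_movie("primary")
  path <- tempfile(fileext = ".tif")
  sub <- fix$movie$tcr
  sub$frames <- sub$frames[, , 1:3, drop = FALSE]
  write_stack_tiff(sub, path)
  back <- read_stack_tiff(path)
  expect_equal(back$pixel_size, sub$pixel_size, tolerance = 1e-4)
  expect_equal(back$frame_interval, sub$frame_interval, tolerance = 1e-6)
  expect_equal(back$frames, round(sub$frames), tolerance = 1e-8)
  expect_equal(back$channel, "tcr")
  unlink(path)
})
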